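#' Run the simulate-then-analyze pipeline from a configuration
#'
#' End-to-end demonstration pipeline on synthetic data: simulate a
#' multi-strain half-sib cohort whose latent trait drives each fish's
#' spot intensity, render one flank image per fish, quantify spots in the
#' standardized ROI, compute ANN clustering ratios, apply the exclusion
#' rules, summarize by strain/family, and (optionally) run the
#' variance-component QTL scan with a permutation threshold on the
#' measured spot density.  Stage outputs are written to `out_dir` and a
#' run manifest (seeds, config snapshot, file digests, exclusion log,
#' package version) is written last.
#'
#' Configuration schema (YAML file or named list; unknown top-level keys
#' are an error; all keys except `seed` and `out_dir` optional):
#' \describe{
#'   \item{seed}{integer; single global seed, split deterministically per
#'     stage (pattern/render/cohort/permutations).}
#'   \item{out_dir}{output directory, created if needed.}
#'   \item{strains}{character vector of strain labels (default 3).}
#'   \item{n_families_per_cross, n_offspring_per_family}{design sizes
#'     (default 4 x 10).}
#'   \item{map}{list `n_lg`, `markers_per_lg`, `spacing_cM` (default
#'     3 x 4 at 25 cM).}
#'   \item{variance_fractions}{named list/vector (strain, polygenic, qtl,
#'     residual), summing to 1.}
#'   \item{base_density}{median spot intensity, spots/cm^2 (default 1.5).}
#'   \item{window_cm}{pattern window `c(width, height)` (default 8 x 5).}
#'   \item{render}{list `scale`, `radius_mean`, `noise_sd`.}
#'   \item{quantify}{list `threshold` ("otsu" or a number),
#'     `min_area_cm2`.}
#'   \item{ann}{list `min_points` (default 10).}
#'   \item{scan}{`FALSE`, or a list `n_perm`, `alpha`, `step_cM`.}
#'   \item{write_images}{write per-fish PNGs (default `FALSE`).}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with `cohort`, `summaries`, `shares`,
#'   `scan` (or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = NULL, out_dir = NULL,
    strains = c("Dom", "Hyb", "Wild"),
    n_families_per_cross = 4, n_offspring_per_family = 10,
    map = list(n_lg = 3, markers_per_lg = 4, spacing_cM = 25),
    variance_fractions = c(strain = 0.10, polygenic = 0.20, qtl = 0.05,
                           residual = 0.65),
    base_density = 1.5, window_cm = c(8, 5),
    render = list(scale = 0.05, radius_mean = 0.12, noise_sd = 0.05),
    quantify = list(threshold = "otsu", min_area_cm2 = 0.005),
    ann = list(min_points = 10),
    scan = list(n_perm = 100, alpha = 0.05, step_cM = Inf),
    write_images = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed) || is.null(cfg$out_dir))
    stop("config must provide 'seed' and 'out_dir'")
  vf <- unlist(cfg$variance_fractions)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  # -- simulate ------------------------------------------------------------
  sim <- tryCatch({
    spec <- cohort_spec(
      strains = cfg$strains,
      n_families_per_cross = cfg$n_families_per_cross,
      n_offspring_per_family = cfg$n_offspring_per_family,
      map = gen_map(cfg$map$n_lg, cfg$map$markers_per_lg,
                    cfg$map$spacing_cM),
      variance_fractions = vf, trait = "latent", seed = cfg$seed)
    simulate_cohort(spec)
  }, error = function(e) stage_fail("simulate", e))

  # -- quantify + ann ------------------------------------------------------
  quant <- tryCatch({
    n <- nrow(sim$cohort)
    rows <- vector("list", n)
    spot_rows <- vector("list", n)
    for (i in seq_len(n)) {
      z <- sim$cohort$latent[i]
      pat <- gen_pattern(pattern_spec(
        "poisson", window = cfg$window_cm,
        intensity = cfg$base_density * exp(z),
        seed = cfg$seed + 1000L + i))
      img <- render_spot_image(pat, scale = cfg$render$scale,
                               radius_mean = cfg$render$radius_mean,
                               noise_sd = cfg$render$noise_sd,
                               seed = cfg$seed + 2000L + i)
      if (isTRUE(cfg$write_images))
        write_spot_image(img, file.path(cfg$out_dir,
                                        paste0(sim$cohort$id[i], ".png")))
      thr <- cfg$quantify$threshold
      q <- quantify_image(img,
                          method = if (identical(thr, "otsu")) "otsu"
                                   else "fixed",
                          fixed_threshold = if (identical(thr, "otsu")) NULL
                                            else as.numeric(thr),
                          min_area_cm2 = cfg$quantify$min_area_cm2)
      ann <- if (q$spot_count >= max(cfg$ann$min_points, 2))
        ann_ratio(q$detection$spots, window = cfg$window_cm)$ratio
      else NA_real_
      rows[[i]] <- tibble::tibble(
        id = sim$cohort$id[i], roi_area_cm2 = q$roi_area_cm2,
        spot_count = q$spot_count, spot_density = q$spot_density,
        ann_ratio = ann)
      sp <- q$detection$spots
      if (nrow(sp)) sp$image_id <- sim$cohort$id[i]
      spot_rows[[i]] <- sp
    }
    cohort <- cbind(sim$cohort, do.call(rbind, rows)[-1])
    list(cohort = tibble::as_tibble(cohort),
         spots = do.call(rbind, spot_rows))
  }, error = function(e) stage_fail("quantify", e))

  cohort <- quant$cohort
  excl_density <- apply_exclusions(cohort, "density")
  excl_log <- attr(excl_density, "exclusion_log")
  excl_ann <- apply_exclusions(cohort, "ann")
  excl_log <- rbind(excl_log, attr(excl_ann, "exclusion_log"))

  # -- group statistics ----------------------------------------------------
  stats_out <- tryCatch({
    summaries <- group_summaries(excl_density, "strain", "spot_density")
    fam <- apply_exclusions(excl_density, "family_model")
    excl_log <- rbind(excl_log, attr(fam, "exclusion_log"))
    shares <- strain_family_shares(fam, "spot_density")
    list(summaries = summaries, shares = shares)
  }, error = function(e) stage_fail("report", e))

  # -- optional QTL scan ---------------------------------------------------
  scan_out <- NULL
  if (!isFALSE(cfg$scan)) {
    scan_out <- tryCatch({
      sc <- scan_genome(excl_density, sim$genotypes, sim$map,
                        sim$pedigree, trait = "spot_density",
                        step_cM = cfg$scan$step_cM)
      permutation_threshold(sc, n_perm = cfg$scan$n_perm,
                            alpha = cfg$scan$alpha,
                            seed = cfg$seed + 3000L)
    }, error = function(e) stage_fail("scan-qtl", e))
  }

  # -- outputs and manifest ------------------------------------------------
  cohort_path <- file.path(cfg$out_dir, "cohort.csv")
  write_cohort(cohort, cohort_path)
  spots_path <- file.path(cfg$out_dir, "spots.csv")
  write_cohort(quant$spots, spots_path)
  summary_path <- file.path(cfg$out_dir, "strain_summaries.tsv")
  write_cohort(stats_out$summaries, summary_path)
  scan_path <- NULL
  if (!is.null(scan_out)) {
    scan_path <- file.path(cfg$out_dir, "scan.tsv")
    write_scan_results(scan_out, scan_path)
  }
  results <- list(
    variance_shares = as.numeric(stats_out$shares),
    n_fish = nrow(cohort),
    n_excluded = nrow(excl_log),
    top_hit = if (!is.null(scan_out))
      list(linkage_group = scan_out$top$linkage_group,
           pos_cM = scan_out$top$pos_cM, lrt = scan_out$top$lrt,
           threshold = scan_out$threshold, genomewide_p = scan_out$top_p)
      else NULL)
  jsonlite::write_json(results, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(cohort_path, spots_path, summary_path, scan_path)
  manifest <- list(
    command = "run_pipeline",
    config = cfg[setdiff(names(cfg), "out_dir")],
    seed = cfg$seed,
    stage_seeds = list(cohort = cfg$seed, patterns = cfg$seed + 1000L,
                       render = cfg$seed + 2000L,
                       permutations = cfg$seed + 3000L),
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files))),
    exclusions = as.list(stats::setNames(excl_log$reason, excl_log$id)),
    software_version = as.character(utils::packageVersion("salmospot")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, summaries = stats_out$summaries,
                 shares = stats_out$shares, scan = scan_out,
                 manifest = manifest))
}
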