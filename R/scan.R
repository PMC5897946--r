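#' Likelihood-ratio test for a QTL at one genomic position
#'
#' Compares the full model (fixed effects + polygenic effect with
#' covariance `A` + QTL effect with covariance `ibd` + residual) to the
#' polygenic-only model by restricted likelihood:
#' `LRT = 2 (lR_full - lR_null)`, floored at zero.  The full model is
#' started from the null-model optimum (with a near-zero QTL variance) as
#' well as from an equal split, so its restricted likelihood can never
#' fall below the null's beyond optimizer tolerance.
#'
#' @param y,X Response and fixed-effect design (see [fit_vc_model()]).
#' @param A Additive (numerator) relationship matrix.
#' @param ibd IBD matrix at the tested position.
#' @param fit_null Optional pre-fitted polygenic-only `vc_fit` (reused
#'   across positions in a scan).
#' @return List: `lrt`, `fit_full`, `fit_null`.
#' @export
lrt_at_position <- function(y, X, A, ibd, fit_null = NULL) {
  if (is.null(fit_null))
    fit_null <- fit_vc_model(y, X, list(polygenic = A))
  s <- fit_null$sigma2
  start <- c(max(s[["polygenic"]], 1e-6 * sum(s)),
             1e-6 * sum(s),
             max(s[["residual"]], 1e-6 * sum(s)))
  fit_full <- fit_vc_model(y, X, list(polygenic = A, qtl = ibd),
                           start = start, check_psd = FALSE)
  list(lrt = max(0, 2 * (fit_full$loglik - fit_null$loglik)),
       fit_full = fit_full, fit_null = fit_null)
}

# Internal: precompute everything a scan needs so permutations only swap y.
# The data are laid out block-wise (pedigree connected components) for the
# compiled profiled-REML evaluator.
prepare_scan <- function(y, X, A, ibd_list) {
  n <- length(y)
  blocks <- vc_blocks(list(A))
  cpp_blocks <- lapply(blocks, function(ix) {
    list(ix = as.integer(ix), X = X[ix, , drop = FALSE],
         A = A[ix, ix, drop = FALSE],
         P = lapply(ibd_list, function(P) P[ix, ix, drop = FALSE]))
  })
  ps <- list(blocks = unname(cpp_blocks), n = n, p = ncol(X),
             npos = length(ibd_list))
  ps$ptr <- .scan_prepare_cpp(ps$blocks, n, ps$p, ps$npos)
  ps
}

# Internal: LRT profile for one response vector on a prepared scan.
# `thorough` adds extra optimizer starts for the full model; permutation
# responses use the single warm start, which is where the permuted-null
# optimum lives.  The external pointer does not survive serialization, so
# rebuild it on demand.
scan_lrt <- function(ps, y, thorough = TRUE) {
  if (is.null(ps$ptr) || .ptr_is_null(ps$ptr))
    ps$ptr <- .scan_prepare_cpp(ps$blocks, ps$n, ps$p, ps$npos)
  .scan_lrt_cpp(ps$ptr, y, thorough)
}

#' Genome scan for a QTL by variance-component LRT
#'
#' Fits the polygenic-only model once, then the full model at every
#' position of a grid (each marker plus regular `step_cM` steps on every
#' linkage group), using position-wise IBD matrices reconstructed from
#' phased parental origins.  Fixed effects default to intercept + strain.
#'
#' @param cohort Phenotype table with `id`, `strain` and the trait column.
#' @param genotypes Dosage matrix (individuals x markers).
#' @param map Genetic map.
#' @param pedigree Pedigree covering the cohort.
#' @param trait Name of the phenotype column (default `"phenotype"`).
#' @param fixed Model formula for fixed effects (default `~ strain`; use
#'   `~ 1` for none).
#' @param step_cM Grid step between markers (default 5; `Inf` scans
#'   markers only).
#' @param assignment Optional pre-computed [phase_offspring()] result.
#' @return Object of class `scan_result`: `table` (tibble
#'   `linkage_group`, `pos_cM`, `lrt`), `top` (position and LRT of the
#'   maximum), plus the ingredients needed by [permutation_threshold()].
#' @export
scan_genome <- function(cohort, genotypes, map, pedigree,
                        trait = "phenotype", fixed = ~strain,
                        step_cM = 5, assignment = NULL) {
  validate_map(map)
  if (!trait %in% names(cohort)) stop("trait column not found: ", trait)
  missing_ids <- setdiff(cohort$id, rownames(genotypes))
  if (length(missing_ids))
    stop("individuals without genotypes: ",
         paste(missing_ids, collapse = ", "))
  keep <- !is.na(cohort[[trait]])
  cohort <- cohort[keep, , drop = FALSE]
  y <- cohort[[trait]]
  X <- stats::model.matrix(fixed, data = cohort)
  if (is.null(assignment))
    assignment <- phase_offspring(pedigree, genotypes, map)
  A <- additive_relationship(pedigree)[cohort$id, cohort$id]
  grid <- scan_grid(map, step_cM)
  ibd_list <- lapply(seq_len(nrow(grid)), function(i)
    ibd_matrix(assignment, pedigree, grid$linkage_group[i], grid$pos_cM[i],
               ids = cohort$id))
  ps <- prepare_scan(y, X, A, ibd_list)
  lrt <- scan_lrt(ps, y)
  tab <- tibble::tibble(linkage_group = grid$linkage_group,
                        pos_cM = grid$pos_cM, lrt = lrt)
  top <- tab[which.max(tab$lrt), ]
  structure(list(table = tab, top = top, trait = trait,
                 prepared = ps, y = y, ids = cohort$id),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("QTL scan over %d positions; top LRT %.3f at %s %.1f cM\n",
              nrow(x$table), x$top$lrt, x$top$linkage_group, x$top$pos_cM))
  if (!is.null(x$threshold))
    cat(sprintf("genome-wide %.0f%% threshold %.3f (n_perm = %d), top p = %.4g\n",
                100 * (1 - x$alpha), x$threshold, x$n_perm, x$top_p))
  invisible(x)
}

# marker positions plus a regular grid per linkage group
scan_grid <- function(map, step_cM) {
  do.call(rbind, lapply(split(map, map$linkage_group), function(m) {
    pos <- m$pos_cM
    if (is.finite(step_cM))
      pos <- sort(unique(c(pos, seq(min(pos), max(pos), by = step_cM))))
    tibble::tibble(linkage_group = m$linkage_group[1], pos_cM = pos)
  }))
}

#' Genome-wide significance threshold by phenotype permutation
#'
#' Churchill-Doerge resampling: the phenotype vector is shuffled against
#' the (pedigree, genotype, fixed-effect) structure `n_perm` times, the
#' whole scan is re-run on each shuffle, and the maximum LRT per shuffle
#' is recorded.  The threshold is the smallest observed maximum whose
#' empirical exceedance is at most `alpha`; the genome-wide p-value of an
#' observed LRT is `(1 + #(max >= observed)) / (n_perm + 1)`.
#'
#' @param scan A `scan_result` from [scan_genome()].
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Genome-wide type-I error rate (0 < alpha < 1).
#' @param seed Integer seed for the shuffles.
#' @return The `scan_result` augmented with `threshold`, `alpha`,
#'   `n_perm`, `perm_max` (the resampled maxima) and `top_p`.
#' @export
permutation_threshold <- function(scan, n_perm = 1000, alpha = 0.05,
                                  seed = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (floor(alpha * n_perm) < 1)
    stop("n_perm too small for the requested alpha quantile")
  run <- function() {
    vapply(seq_len(n_perm), function(i) {
      max(scan_lrt(scan$prepared, sample(scan$y), thorough = FALSE))
    }, numeric(1))
  }
  perm_max <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  srt <- sort(perm_max, decreasing = TRUE)
  scan$threshold <- srt[floor(alpha * n_perm)]
  scan$alpha <- alpha
  scan$n_perm <- n_perm
  scan$perm_max <- perm_max
  scan$top_p <- (1 + sum(perm_max >= scan$top$lrt)) / (n_perm + 1)
  scan
}

#' Offspring means by inherited parental allele at a position
#'
#' For one parent that is informative at a position, groups its offspring
#' by which parental haplotype they inherited (posterior origin
#' probability beyond `min_prob` either way) and contrasts the group
#' means of a trait, optionally stratified by the mate's strain
#' (farm/wild background).
#'
#' @param cohort Phenotype table (`id`, `strain`, trait column).
#' @param assignment A `haplo_assignment`.
#' @param pedigree Pedigree table.
#' @param parent Parent id.
#' @param linkage_group,pos_cM Position of interest.
#' @param trait Trait column name.
#' @param min_prob Posterior certainty required to assign an offspring to
#'   a haplotype group (default 0.8).
#' @param by_mate Stratify by mate strain (default `FALSE`).
#' @return Tibble with one row per haplotype group (and stratum):
#'   `haplotype`, `n`, `mean`, `sd`, plus attributes `t`, `df`, `p_value`
#'   from a Welch two-group test in the unstratified case.
#' @export
allele_contrast <- function(cohort, assignment, pedigree, parent,
                            linkage_group, pos_cM, trait = "phenotype",
                            min_prob = 0.8, by_mate = FALSE) {
  op <- origin_probs(assignment, linkage_group, pos_cM)
  as_sire <- assignment$sire == parent
  as_dam <- assignment$dam == parent
  if (!any(as_sire | as_dam)) stop("parent has no phased offspring: ", parent)
  p <- ifelse(as_sire, op[, "p_sire"], ifelse(as_dam, op[, "p_dam"], NA))
  names(p) <- assignment$offspring
  p <- p[as_sire | as_dam]
  grp <- ifelse(p >= min_prob, 1L, ifelse(p <= 1 - min_prob, 2L, NA_integer_))
  if (all(is.na(grp)) || length(unique(stats::na.omit(grp))) < 2)
    stop("parent is uninformative at this position: ", parent)
  df <- cohort[match(names(p), cohort$id), , drop = FALSE]
  df$haplotype <- grp
  df <- df[!is.na(df$haplotype) & !is.na(df[[trait]]), , drop = FALSE]
  if (by_mate) {
    mate <- ifelse(pedigree$sire[match(df$id, pedigree$id)] == parent,
                   pedigree$dam[match(df$id, pedigree$id)],
                   pedigree$sire[match(df$id, pedigree$id)])
    df$mate_strain <- pedigree$strain[match(mate, pedigree$id)]
    groups <- split(df, list(df$mate_strain, df$haplotype), drop = TRUE)
  } else groups <- split(df, df$haplotype)
  out <- do.call(rbind, lapply(groups, function(g)
    tibble::tibble(haplotype = g$haplotype[1],
                   mate_strain = if (by_mate) g$mate_strain[1] else NA,
                   n = nrow(g), mean = mean(g[[trait]]),
                   sd = stats::sd(g[[trait]]))))
  if (!by_mate && length(unique(df$haplotype)) == 2 &&
      all(table(df$haplotype) >= 2)) {
    tt <- stats::t.test(df[[trait]] ~ df$haplotype)
    attr(out, "t") <- unname(tt$statistic)
    attr(out, "df") <- unname(tt$parameter)
    attr(out, "p_value") <- tt$p.value
  }
  out
}
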