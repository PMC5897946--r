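# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the flood fill is queue-based pure R, the
# kinship oracle is brute-force gene dropping.

# count 8-connected foreground components by explicit flood fill
flood_fill_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j] || seen[i, j]) next
      count <- count + 1L
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      while (length(queue)) {
        cur <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ni <- cur[1] + di; nj <- cur[2] + dj
          if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
          if (mask[ni, nj] && !seen[ni, nj]) {
            seen[ni, nj] <- TRUE
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
    }
  }
  count
}

# brute-force additive relationship between two ids: average allele-sharing
# over `ndrop` single-locus gene drops, times 2 (a_ij = 2 * kinship)
gene_drop_relationship <- function(ped, id_a, id_b, ndrop = 20000) {
  ord <- validate_pedigree(ped)
  n <- nrow(ord)
  si <- match(ord$sire, ord$id)
  di <- match(ord$dam, ord$id)
  ia <- match(id_a, ord$id); ib <- match(id_b, ord$id)
  share <- numeric(ndrop)
  for (r in seq_len(ndrop)) {
    h1 <- integer(n); h2 <- integer(n)
    nxt <- 0L
    for (i in seq_len(n)) {
      if (is.na(si[i])) {
        h1[i] <- nxt + 1L; h2[i] <- nxt + 2L; nxt <- nxt + 2L
      } else {
        h1[i] <- if (stats::runif(1) < 0.5) h1[si[i]] else h2[si[i]]
        h2[i] <- if (stats::runif(1) < 0.5) h1[di[i]] else h2[di[i]]
      }
    }
    a <- c(h1[ia], h2[ia]); b <- c(h1[ib], h2[ib])
    share[r] <- mean(outer(a, b, `==`))
  }
  2 * mean(share)
}

# vector with exact sample mean and sd
exact_norm <- function(n, mean, sd) {
  x <- stats::rnorm(n)
  mean + sd * (x - mean(x)) / stats::sd(x)
}

# small hand-built nuclear-family genotype fixture builder
family_genotypes <- function(sire_g, dam_g, off_g, markers, ped_ids) {
  G <- rbind(sire_g, dam_g, off_g)
  rownames(G) <- ped_ids
  colnames(G) <- markers
  G
}
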