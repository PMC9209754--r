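# Small panels and architectures built in code for the unit tests.

# presence matrix from a list line_id -> character vector of loci
make_panel <- function(layout, loci, control = "CTL") {
  pres <- matrix(FALSE, length(layout), length(loci),
                 dimnames = list(names(layout), loci))
  for (id in names(layout)) pres[id, layout[[id]]] <- TRUE
  genotype_panel(pres, control = control)
}

# 3-locus panel: SSSLs for each locus plus a 2-QTL and a 3-QTL pyramid
toy_panel <- function() {
  loci <- c("qA-sat", "qB-gla", "qC-glu")
  make_panel(c(
    list(CTL = character(0)),
    stats::setNames(as.list(loci), paste0("SSSL-", loci)),
    list(`2QL-1` = loci[1:2], `3QL-1` = loci)
  ), loci)
}

toy_config <- function(...) {
  args <- utils::modifyList(
    list(P0 = 30, additive = c("qA-sat" = 15, "qB-gla" = 18, "qC-glu" = 21),
         epistasis = list(model = "none"), noise_sd = 0, seasons = 3L,
         seed = 11L),
    list(...))
  do.call(architecture_config, args)
}

# classical recursive Duncan procedure: independent oracle for the letter
# partition (tests homogeneous blocks by stepwise range recursion)
duncan_oracle_blocks <- function(ms, lsr) {
  k <- length(ms)
  blocks <- list()
  recurse <- function(i, j) {
    if (i > j) return()
    if (i == j) { blocks[[length(blocks) + 1L]] <<- c(i, j); return() }
    span <- j - i + 1L
    if (ms[i] - ms[j] <= lsr[[as.character(span)]]) {
      blocks[[length(blocks) + 1L]] <<- c(i, j)
    } else {
      recurse(i, j - 1L)
      recurse(i + 1L, j)
    }
  }
  recurse(1L, k)
  # drop blocks contained in another; unique; sort
  keep <- vapply(seq_along(blocks), function(a)
    !any(vapply(seq_along(blocks), function(b)
      b != a && blocks[[b]][1L] <= blocks[[a]][1L] &&
        blocks[[b]][2L] >= blocks[[a]][2L] &&
        !identical(blocks[[b]], blocks[[a]]), TRUE)), TRUE)
  blocks <- unique(blocks[keep])
  blocks[order(vapply(blocks, `[`, 1L, 1L), vapply(blocks, `[`, 1L, 2L))]
}

# brute-force 1-D k-partition over all contiguous splits of sorted values
best_contiguous_partition <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  splits <- utils::combn(n - 1L, k - 1L)
  best <- NULL; best_ss <- Inf
  for (c_ in seq_len(ncol(splits))) {
    b <- c(0L, splits[, c_], n)
    ss <- 0
    for (j in seq_len(k)) {
      seg <- x[(b[j] + 1L):b[j + 1L]]
      ss <- ss + sum((seg - mean(seg))^2)
    }
    if (ss < best_ss - 1e-12) { best_ss <- ss; best <- b }
  }
  list(bounds = best, ss = best_ss)
}
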