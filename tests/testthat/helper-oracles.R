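# Independent brute-force oracles: direct double loops recomputing shared
# sites from the columns, kept free of the package's vectorized path.

bruteCscore <- function(occ) {
  R <- nrow(occ)
  tot <- 0
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      s <- sum(occ[i, ] == 1 & occ[j, ] == 1)
      tot <- tot + (sum(occ[i, ]) - s) * (sum(occ[j, ]) - s)
    }
  }
  tot / (R * (R - 1) / 2)
}

brutePairCount <- function(occ) {
  R <- nrow(occ)
  n <- 0L
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      s <- sum(occ[i, ] == 1 & occ[j, ] == 1)
      if ((sum(occ[i, ]) - s) * (sum(occ[j, ]) - s) > 0) n <- n + 1L
    }
  }
  n
}

randomIncidence <- function(nr, nc, fill = 0.4) {
  occ <- matrix(rbinom(nr * nc, 1, fill), nr, nc,
                dimnames = list(paste0("sp", seq_len(nr)),
                                paste0("site", seq_len(nc))))
  occ
}

marginsOf <- function(m) {
  mp <- margins(m)
  list(r = rowTotals(mp), c = colTotals(mp))
}
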