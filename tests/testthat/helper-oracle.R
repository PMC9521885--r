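# Independent straight-loop reference implementation of the scoring chain.
# Deliberately written with explicit loops and no shared code with the
# package internals; used to cross-check A, D, SS, SDS and zip means.

oracle_scores <- function(intervals, units, min_baseline = 4, log_base = 10) {
  rows <- list()
  for (u in unique(intervals$unit_id)) {
    g <- intervals[intervals$unit_id == u & intervals$open, ]
    ci <- c(); bi <- c()
    for (i in seq_len(nrow(g))) {
      if (g$complaint[i]) ci <- c(ci, g$intensity[i]) else bi <- c(bi, g$intensity[i])
    }
    if (length(ci) < 1 || length(bi) < min_baseline) next
    A <- sum(ci) / length(ci)
    B <- sum(bi) / length(bi)
    if (is.na(B) || B <= 0 || A <= 0) next
    D <- (A - B) / B
    SS <- D * (log(A) / log(log_base))
    rows[[u]] <- list(unit_id = u, A = A, D = D, SS = SS)
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  mn <- min(df$SS); mx <- max(df$SS)
  df$SDS <- abs(1 - (df$SS - mn) / (mx - mn)) * 100
  df$zip <- units$zip[match(df$unit_id, units$unit_id)]
  rownames(df) <- NULL
  df
}

oracle_zip_means <- function(scored) {
  out <- list()
  for (z in sort(unique(scored$zip))) {
    vals <- scored$SDS[scored$zip == z]
    out[[z]] <- list(zip = z, SDS_z = sum(vals) / length(vals), n_units = length(vals))
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  rownames(df) <- NULL
  df
}
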