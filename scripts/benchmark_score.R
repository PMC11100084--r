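#!/usr/bin/env Rscript
# Informational benchmark: spectral fast path vs QR reference for the
# permuted score statistics. Writes a TSV of timings to stdout or --out.

suppressPackageStartupMessages(library(screenperm))

args <- commandArgs(trailingOnly = TRUE)
out <- if (length(args) >= 2 && args[1] == "--out") args[2] else ""

set.seed(1)
rows <- list()
for (n in c(2000, 10000)) {
  for (q in c(2, 6)) {
    Z <- cbind(1, matrix(rnorm(n * (q - 1)), n))
    Y <- rnbinom(n, size = 4, mu = exp(0.5 + 0.2 * Z[, 2]))
    fit <- fit_null_glm(Y, Z)
    pc <- precompute_score(fit, Z)
    t_ <- round(0.04 * n)
    B <- 500
    bank <- resample_bank(n, 1, paste0("bench", n, "_", q))
    o <- screenperm:::bank_orderings(bank, B)
    t_spec <- system.time(
      screenperm:::score_stats_permuted(pc, o, t_))[["elapsed"]]
    t_qr <- system.time(for (b in seq_len(min(B, 50))) {
      x <- numeric(n)
      x[o[seq_len(t_), b]] <- 1
      score_stat_qr(x, fit, Z)
    })[["elapsed"]] * B / min(B, 50)
    rows[[length(rows) + 1]] <- data.frame(
      n = n, q = q, t = t_, B = B,
      spectral_sec = t_spec, qr_sec_extrapolated = t_qr)
  }
}
tab <- do.call(rbind, rows)
if (nzchar(out)) {
  write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
} else {
  print(tab, row.names = FALSE)
}
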