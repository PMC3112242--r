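# internal helpers

# run expr with a temporarily seeded RNG, restoring prior state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stable per-unit sub-seed derived from a master seed (kept < 2^31)
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483563 + 1
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# fixed-format number rendering so outputs are byte-stable across runs
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

write_tsv_stable <- function(df, path) {
  df2 <- df
  for (nm in names(df2)) {
    if (is.numeric(df2[[nm]]) && !is.integer(df2[[nm]]))
      df2[[nm]] <- fmt_num(df2[[nm]])
  }
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", na = "NA")
  invisible(path)
}
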