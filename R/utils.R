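# Internal helpers.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Majority vote with deterministic alphabetical tie-break.
majorityLabel <- function(labels) {
  tb <- table(labels)
  names(tb)[which.max(tb)]
}

# Map a p-value to the conventional star annotation
# (ns > 0.05, * < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001).

#' Significance stars for p-values
#'
#' @param p numeric vector of p-values.
#' @return character vector in `c("ns", "*", "**", "***", "****")`.
#' @examples significanceStars(c(0.2, 0.03, 0.004, 2e-4, 5e-6))
#' @export
significanceStars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}
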