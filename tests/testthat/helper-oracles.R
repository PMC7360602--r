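# Independent brute-force oracles.  These deliberately re-derive results
# with naive loops and explicit arithmetic, sharing no code with the
# package's implementations.

# Histogram-mode oracle: plausible filter, 3-MAD filter, round half away
# from zero, exhaustive count, tie nearest-median-then-smaller.
oracle_mode_estimate <- function(grams, config) {
  lo <- config$plausible_weight_g[1]; hi <- config$plausible_weight_g[2]
  kept <- grams[vapply(grams, function(g) is.finite(g) && g >= lo && g <= hi,
                       TRUE)]
  if (length(kept) == 0) return(NULL)
  med <- median(kept)
  madv <- median(abs(kept - med)) * 1.4826
  kept2 <- if (madv > 0)
    kept[vapply(kept, function(g) abs(g - med) <= 3 * madv, TRUE)]
  else kept[vapply(kept, function(g) g == med, TRUE)]
  p <- 10^config$weight_round_dp
  r <- sign(kept2) * floor(abs(kept2) * p + 0.5 + 1e-9) / p
  counter <- new.env(parent = emptyenv())
  for (v in r) {
    k <- sprintf("%.10f", v)
    n_old <- get0(k, envir = counter, ifnotfound = 0L)
    assign(k, n_old + 1L, envir = counter)
  }
  keys <- ls(counter)
  cnts <- vapply(keys, get, 0L, envir = counter)
  best_n <- max(cnts)
  cand <- as.numeric(keys[cnts == best_n])
  if (length(cand) > 1) {
    m <- median(r)
    d <- abs(cand - m)
    cand <- cand[d == min(d)]
    cand <- min(cand)
  }
  list(grams = cand, n_retained = length(r))
}

# Loop-based tally of drop events per mouse-day.
oracle_drop_tally <- function(events, origin_date) {
  out <- list()
  for (i in seq_len(nrow(events))) {
    code <- events$code[i]
    if (code != "DROP_WATER" && code != "DROP_DRUG") next
    d <- as.character(as.Date(events$time[i], tz = "UTC"))
    k <- paste(events$tag[i], d, code)
    out[[k]] <- if (is.null(out[[k]])) 1L else out[[k]] + 1L
  }
  out
}

# Explicit product-moment correlation from sums (no call to cor()).
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

make_profiles <- function(n_treat, n_ctrl, dose = 1) {
  profs <- c(
    lapply(seq_len(n_treat), function(i)
      mouse_profile(sprintf("T%02d", i), "treatment", dose_mg_per_kg = dose)),
    lapply(seq_len(n_ctrl), function(i)
      mouse_profile(sprintf("C%02d", i), "control")))
  names(profs) <- vapply(profs, `[[`, "", "rfid_tag")
  profs
}
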