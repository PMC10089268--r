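# Independent brute-force oracles used across the suite. These stay
# deliberately naive (lm() per segment, explicit loops) so they share no
# code path with the implementation they check.

# minimum piecewise SSE over every breakpoint placement, lm() per segment
bf_piecewise_sse <- function(y, k, min_len = 2L) {
  n <- length(y)
  seg_sse <- function(i, j) {
    x <- i:j
    sum(stats::lm(y[i:j] ~ x)$residuals^2)
  }
  if (k == 1L) return(seg_sse(1L, n))
  best <- Inf
  starts <- utils::combn(2:n, k - 1L) # start indices of segments 2..k
  for (c in seq_len(ncol(starts))) {
    b <- c(1L, starts[, c], n + 1L)
    if (any(diff(b) < min_len)) next
    sse <- 0
    for (s in seq_len(k)) sse <- sse + seg_sse(b[s], b[s + 1L] - 1L)
    best <- min(best, sse)
  }
  best
}

# the stated selection rule, re-implemented naively: most severe current
# flag; ties by longest run of consecutive reds ending at the most
# recent week; remaining ties by position
bf_select_behaviour <- function(current, history) {
  sev <- c(green = 1, yellow = 2, red = 3)[current]
  runs <- vapply(seq_along(current), function(i) {
    if (current[i] != "red") return(0L)
    r <- 1L
    h <- history[[i]] # oldest first
    for (f in rev(h)) {
      if (identical(f, "red")) r <- r + 1L else break
    }
    r
  }, integer(1))
  best <- which(sev == max(sev))
  best <- best[runs[best] == max(runs[best])]
  best[1]
}

# a one-dimension test catalogue: mission i targets behaviour ids[i]
mini_catalogue <- function(ids, dimension = "diet") {
  tibble::tibble(
    mission_id = seq_along(ids), dimension = dimension,
    target_behaviour_id = ids,
    description = paste("work on", ids),
    mode = "individual", points = 10L, ability = "discipline"
  )
}

mini_flags <- function(ids, flags, dimension = "diet") {
  tibble::tibble(behaviour_id = ids, label = ids, dimension = dimension,
                 variable_id = ids, value = NA_real_,
                 flag = as_flag(flags))
}

# history tibble from a matrix of flags (rows = behaviours, cols = weeks
# oldest..newest)
mini_history <- function(ids, flag_matrix, weeks = NULL) {
  if (is.null(weeks)) {
    weeks <- sprintf("2024-W%02d", seq_len(ncol(flag_matrix)))
  }
  out <- list()
  for (i in seq_along(ids)) {
    out[[i]] <- tibble::tibble(behaviour_id = ids[i], week = weeks,
                               flag = flag_matrix[i, ])
  }
  dplyr::bind_rows(out)
}

# flags across all three dimensions for the default behaviours
full_flags <- function(flags = "green") {
  b <- default_behaviours()
  tibble::tibble(behaviour_id = b$behaviour_id, label = b$label,
                 dimension = b$dimension, variable_id = b$variable_id,
                 value = NA_real_,
                 flag = as_flag(rep(flags, length.out = nrow(b))))
}
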