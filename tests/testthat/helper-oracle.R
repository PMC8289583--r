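# independent brute-force implementation of the boosting recursion over
# enumerated decision stumps; shares no code with the package internals
brute_force_boost <- function(x, y, rounds) {
  x <- as.matrix(x)
  n <- nrow(x)
  classes <- sort(unique(y))
  w <- rep(1 / n, n)
  trace <- list()
  stump_fit <- function(w) {
    best <- NULL
    for (j in seq_len(ncol(x))) {
      vals <- sort(unique(x[, j]))
      if (length(vals) < 2) next
      for (thr in (vals[-1] + vals[-length(vals)]) / 2) {
        left <- x[, j] <= thr
        maj <- function(mask) {
          if (!any(mask)) return(classes[1])
          ww <- sapply(classes, function(cl) sum(w[mask & y == cl]))
          classes[which.max(ww)]
        }
        pred <- ifelse(left, maj(left), maj(!left))
        err <- sum(w[pred != y])
        if (is.null(best) || err < best$err - 1e-15) {
          best <- list(err = err, pred = pred)
        }
      }
    }
    best
  }
  for (m in seq_len(rounds)) {
    st <- stump_fit(w)
    e <- st$err
    ec <- min(max(e, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - ec) / ec)
    trace[[m]] <- list(e = e, alpha = alpha, w = w)
    w <- w * exp(ifelse(st$pred != y, alpha, -alpha))
    w <- w / sum(w)
  }
  trace
}
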