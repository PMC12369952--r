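# Shared fixtures, built in code (no files).  Helpers are sourced once per
# test run, so the small simulated log is computed once.

# the toy two-case log used across I/O and encoding tests
toy_log <- function() {
  event_log(list(
    process_case("c1", c("A", "B"), c(0, 10)),
    process_case("c2", c("A", "C", "B"), c(0, 5, 20))
  ))
}

toy_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c("case_id,activity,timestamp",
               "c1,A,0", "c1,B,10",
               "c2,A,0", "c2,C,5", "c2,B,20"), path)
  path
}

# a small simulated clinic log (60 cases) for module-level tests
fixture_small <- simulate_log(clinic_small_spec(n_cases = 60L, seed = 11L))

# central finite-difference gradient of f at x
num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# independent plain multi-head scaled dot-product attention oracle
plain_attention_oracle <- function(x, wq, wk, wv, n_heads) {
  d <- ncol(wq)
  dh <- d / n_heads
  q <- x %*% wq; k <- x %*% wk; v <- x %*% wv
  out <- matrix(0, nrow(x), d)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    e <- q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE]) / sqrt(dh)
    a <- exp(e - apply(e, 1, max))
    a <- a / rowSums(a)
    out[, cols] <- a %*% v[, cols, drop = FALSE]
  }
  out
}

# definitional recursive Levenshtein oracle (no dynamic program)
lev_recursive <- function(a, b) {
  if (length(a) == 0) return(length(b))
  if (length(b) == 0) return(length(a))
  min(lev_recursive(a[-length(a)], b) + 1,
      lev_recursive(a, b[-length(b)]) + 1,
      lev_recursive(a[-length(a)], b[-length(b)]) +
        (a[length(a)] != b[length(b)]))
}

# all label sequences of length 0..max_len over `labels`
all_sequences <- function(labels, max_len) {
  out <- list(character(0))
  for (l in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(labels), l), stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i) {
      as.character(unlist(grid[i, ]))
    }))
  }
  out
}
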