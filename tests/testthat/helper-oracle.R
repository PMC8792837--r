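# Independent literal-formula implementations of the 13 window features,
# written as plain loops straight from the printed definitions. These act
# as the oracle the packaged (vectorised) implementations are checked
# against; they share no code with R/features.R.

oracle_feature <- function(id, x) {
  n <- length(x)
  switch(id,
    MAV = {
      s <- 0
      for (i in 1:n) s <- s + abs(x[i])
      s / n
    },
    WL = {
      s <- 0
      for (i in 1:(n - 1)) s <- s + abs(x[i + 1] - x[i])
      s
    },
    AAC = {
      s <- 0
      for (i in 1:(n - 1)) s <- s + abs(x[i + 1] - x[i])
      s / n
    },
    SSI = {
      s <- 0
      for (i in 1:n) s <- s + x[i]^2
      s
    },
    RMS = {
      s <- 0
      for (i in 1:n) s <- s + x[i]^2
      sqrt(s / n)
    },
    VAR = {
      xbar <- 0
      for (i in 1:n) xbar <- xbar + x[i]
      xbar <- xbar / n
      s <- 0
      for (i in 1:n) s <- s + (x[i] - xbar)^2
      s / (n - 1)
    },
    STD = {
      xbar <- sum(x) / n
      s <- 0
      for (i in 1:n) s <- s + (x[i] - xbar)^2
      sqrt(s / (n - 1))
    },
    DASDV = {
      s <- 0
      for (i in 1:(n - 1)) s <- s + (x[i + 1] - x[i])^2
      sqrt(s / (n - 1))
    },
    TM3 = {
      s <- 0
      for (i in 1:n) s <- s + x[i]^3
      abs(s / n)
    },
    TM4 = {
      s <- 0
      for (i in 1:n) s <- s + x[i]^4
      abs(s / n)
    },
    TM5 = {
      s <- 0
      for (i in 1:n) s <- s + x[i]^5
      abs(s / n)
    },
    KURT = {
      xbar <- sum(x) / n
      num <- 0
      for (i in 1:n) num <- num + (abs(x[i]) - xbar)^2
      num <- num / n
      den <- 0
      for (i in 1:n) den <- den + x[i]^2
      den <- (den / n)^4
      if (den == 0) 0 else num / den
    },
    LOGD = {
      s <- 0
      for (i in 1:n) s <- s + log(abs(x[i]) + .Machine$double.eps)
      exp(s / n)
    },
    stop("unknown feature id in oracle: ", id))
}

# Brute-force sliding-window count: enumerate every start index and count
# those whose window fits entirely inside the signal.
oracle_window_count <- function(L, W, I) {
  count <- 0L
  start <- 0L
  while (start + W <= L) {
    count <- count + 1L
    start <- start + I
  }
  count
}
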