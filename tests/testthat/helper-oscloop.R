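# Shared fixtures: built in code, deliberately small.

mont19 <- standard1020Positions()

# cached small solution spaces / lead fields (built once per test run)
.fixtures <- new.env()

miniSpace <- function() {
  if (is.null(.fixtures$sp)) .fixtures$sp <- solutionSpace("mini")
  .fixtures$sp
}

miniLeadField <- function() {
  if (is.null(.fixtures$lf))
    .fixtures$lf <- buildLeadField(mont19, miniSpace())
  .fixtures$lf
}

miniOperator <- function() {
  if (is.null(.fixtures$op)) .fixtures$op <- sloretaOperator(miniLeadField())
  .fixtures$op
}

randomRecording <- function(n = 1280, fs = 128, seed = 1, scale = 20) {
  set.seed(seed)
  eegRecording(matrix(rnorm(19 * n), 19) * scale, fs = fs,
               channelLabels = canonical1020Labels())
}

# theta series with a known phase plus a gamma carrier with planted
# modulation depth m
plantedPacPair <- function(n, fs, m, seed = 1) {
  set.seed(seed)
  th <- as.vector(oscloop:::narrowbandNoise(n, fs, 4, 7.5))
  ph <- Arg(oscloop:::analyticSignal(th))
  ga <- as.vector(oscloop:::narrowbandNoise(n, fs, 30.5, 44)) * (1 + m * cos(ph))
  list(theta = th, gamma = ga, phase = ph)
}

# brute-force closure-principle step-down adjustment with Bonferroni local
# tests: adj p_i = max over subsets S containing i of |S| * min_{j in S} p_j
closureAdjust <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- 0
    for (mask in seq_len(2^m - 1)) {
      S <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
      if (!(i %in% S)) next
      best <- max(best, length(S) * min(p[S]))
    }
    adj[i] <- min(1, best)
  }
  adj
}
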