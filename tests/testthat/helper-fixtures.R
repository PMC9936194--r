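# Shared fixtures. Expensive objects (a registered synthetic trial) are
# built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# a small, fast cohort spec for smoke-level tests
tinySpec <- function(...) {
  cohortSpec(nSubjects = 4L, nModesKinematic = 2L, nModesEmg = 2L,
             trueCoefficients = data.frame(mode = 1:2,
                                           weight = c(1.6, -1.2)),
             modeScoreSd = c(0.25, 0.18), seed = 42L, ...)
}

# one generated + registered subject, cached
registeredFixture <- function() {
  if (is.null(.fixtures$reg)) {
    tr <- generateTrial(1L, tinySpec())
    .fixtures$raw <- tr
    .fixtures$reg <- registerSprint(tr$marker)
  }
  list(raw = .fixtures$raw, reg = .fixtures$reg)
}

# a hand-built marker trial: T8 advancing at constant speed, everything
# else laid out statically with small deterministic offsets, the right
# ankle bobbing so stride detection works when needed
constantSpeedTrial <- function(speed = 10, duration = 7, rate = 60,
                               bobAnkle = FALSE) {
  labels <- markerLabels()
  nF <- as.integer(duration * rate) + 1L
  t <- (seq_len(nF) - 1L) / rate
  pos <- array(0, dim = c(nF, 64L, 3L))
  for (m in seq_along(labels)) {
    pos[, m, 1L] <- speed * t + 0.01 * m
    pos[, m, 2L] <- 0.02 * ((m %% 5L) - 2L)
    pos[, m, 3L] <- 0.025 * (m %% 13L)
  }
  # T8 travels exactly through the origin along +x so that both speed
  # definitions (vector norm and derivative-of-norm) agree
  i8 <- match("T8", labels)
  pos[, i8, 1L] <- speed * t
  pos[, i8, 2L] <- 0
  pos[, i8, 3L] <- 0
  if (bobAnkle) {
    ia <- match("RightAnkle", labels)
    pos[, ia, 3L] <- 0.1 + 0.05 * (1 - cos(2 * pi * 2 * t))
  }
  markerTrial(pos, labels, rate,
              list(id = "fix", height = 1.77, sex = 0, age = 25))
}

# independent type-7 quantile oracle (sort + linear interpolation)
quantileOracle <- function(x, q) {
  xs <- sort(x)
  h <- (length(xs) - 1) * q + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# principal angles (degrees) between the column spaces of two bases
principalAnglesDeg <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

# angle (degrees) between two rotation matrices
rotationAngleDeg <- function(R1, R2) {
  Rd <- R1 %*% t(R2)
  acos(min(max((sum(diag(Rd)) - 1) / 2, -1), 1)) * 180 / pi
}

# sinusoid amplitude at a known frequency via least squares
fitSineAmplitude <- function(x, rate, freqHz) {
  t <- (seq_along(x) - 1) / rate
  X <- cbind(sin(2 * pi * freqHz * t), cos(2 * pi * freqHz * t))
  cf <- coef(lm(x ~ X))
  sqrt(cf[2]^2 + cf[3]^2)
}
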