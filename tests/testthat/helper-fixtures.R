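# Shared fixtures: all generated in code, deterministic.

# deterministic structured image pair (identical arithmetic in any stack)
fixtureImagePair <- function(n = 128L) {
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  x <- 0.5 + 0.5 * sin(i / 7) * cos(j / 11)
  g <- ((37 * i + 17 * j) %% 101) / 101
  list(x = x, xhat = 0.9 * x + 0.1 * g)
}

deskProtocol <- function() parseProtocol("30s×2+60s×2+150s×2")

deskGeometry <- function(n = 32L, nAngles = 40L)
  systemGeometry(n, nAngles, c(n, n), pixelSizeMM = 2.2)

# small cached system matrices (built once per test run)
.fixtureEnv <- new.env(parent = emptyenv())
cachedSysmat <- function(n = 32L, nAngles = 40L) {
  key <- paste0("sm", n, "_", nAngles)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- buildSystemMatrix(deskGeometry(n, nAngles))
  .fixtureEnv[[key]]
}

# disk image in a DynamicImage wrapper (single frame)
diskImage <- function(n, radiusPx, pixelMM = 2.2, value = 1) {
  ctr <- (n + 1) / 2
  xs <- (col(matrix(0, n, n)) - ctr) * pixelMM
  ys <- (row(matrix(0, n, n)) - ctr) * pixelMM
  disk <- (xs^2 + ys^2 <= (radiusPx * pixelMM)^2) * value
  new("DynamicImage", data = array(disk, c(n, n, 1)),
      protocol = scanProtocol(60), tracer = "disk")
}

# adaptive-step ODE oracle for the two-tissue compartment model
ode2TCMOracle <- function(params, cpFun, tGridS) {
  deriv <- function(tt, y, p) {
    list(c(p[1] * cpFun(tt) - (p[2] + p[3]) * y[1] + p[4] * y[2],
           p[3] * y[1] - p[4] * y[2]))
  }
  sol <- deSolve::ode(c(0, 0), tGridS / 60, deriv, params,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  sol[, 2] + sol[, 3]
}
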