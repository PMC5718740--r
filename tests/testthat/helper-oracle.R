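# Independent homogeneous-water photon Monte Carlo oracle, written in plain
# vectorised R with R's own RNG and a collision-density (analog) kerma
# estimator -- deliberately different algorithms from the package's C++
# track-length ray tracer. Scores collision kerma in concentric spherical
# shells around a point-isotropic source in an infinite water medium
# (photons killed beyond r_max).
oracle_water_mc <- function(n = 2e5, seed = 99, shells = seq(0, 6, by = 0.1),
                            r_max = 8, cutoff = 0.06) {
  set.seed(seed)
  wat <- water()
  sp <- ir192_spectrum()
  mu_of <- function(E, ch) linear_mu(wat, E, ch)
  f_kn <- function(E) kn_transfer_fraction(E)

  E <- sample(sp$energy_mev, n, replace = TRUE, prob = sp$intensity)
  pos <- matrix(0, n, 3)
  ct <- stats::runif(n, -1, 1)
  ph <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(1 - ct^2)
  dir <- cbind(st * cos(ph), st * sin(ph), ct)

  tall <- numeric(length(shells) - 1)
  deposit <- function(r, e_dep) {
    b <- findInterval(r, shells, rightmost.closed = TRUE)
    ok <- b >= 1 & b <= length(tall) & r < max(shells)
    if (any(ok)) {
      agg <- tapply(e_dep[ok], b[ok], sum)
      tall[as.integer(names(agg))] <<- tall[as.integer(names(agg))] + agg
    }
  }

  for (gen in 1:60) {
    if (length(E) == 0) break
    mu_pe <- mu_of(E, "photoelectric")
    mu_in <- mu_of(E, "incoherent")
    mu_co <- mu_of(E, "coherent")
    mu <- mu_pe + mu_in + mu_co
    s <- stats::rexp(length(E), mu)
    pos <- pos + dir * s
    r <- sqrt(rowSums(pos^2))
    inside <- r < r_max
    # collision kerma estimator: expected energy transfer per collision
    ftr <- (mu_pe + f_kn(E) * mu_in) / mu
    deposit(r[inside], (E * ftr)[inside])

    E <- E[inside]; pos <- pos[inside, , drop = FALSE]
    dir <- dir[inside, , drop = FALSE]
    mu_pe <- mu_pe[inside]; mu_in <- mu_in[inside]; mu_co <- mu_co[inside]
    mu <- mu[inside]
    if (length(E) == 0) break

    u <- stats::runif(length(E)) * mu
    is_pe <- u < mu_pe
    is_co <- !is_pe & u < mu_pe + mu_co
    is_in <- !is_pe & !is_co

    # Compton: vectorised Klein-Nishina rejection on x = E'/E
    if (any(is_in)) {
      k <- E[is_in] / 0.51099895
      x <- rep(NA_real_, length(k))
      todo <- seq_along(k)
      while (length(todo) > 0) {
        xmin <- 1 / (1 + 2 * k[todo])
        xx <- xmin + (1 - xmin) * stats::runif(length(todo))
        cth <- 1 + 1 / k[todo] - 1 / (k[todo] * xx)
        f <- xx + 1 / xx - (1 - cth^2)
        acc <- stats::runif(length(todo)) * (xmin + 1 / xmin) <= f
        x[todo[acc]] <- xx[acc]
        todo <- todo[!acc]
      }
      cth <- 1 + 1 / k - 1 / (k * x)
      # rotate scattered direction about the incident direction
      d0 <- dir[is_in, , drop = FALSE]
      sth <- sqrt(pmax(1 - cth^2, 0))
      phi <- stats::runif(length(k), 0, 2 * pi)
      # build an orthonormal frame per photon
      ref <- cbind(rep(1, length(k)), 0, 0)
      swap <- abs(d0[, 1]) > 0.9
      ref[swap, ] <- matrix(c(0, 1, 0), nrow = sum(swap), ncol = 3,
                            byrow = TRUE)
      u1 <- ref - d0 * rowSums(ref * d0)
      u1 <- u1 / sqrt(rowSums(u1^2))
      u2 <- cbind(d0[, 2] * u1[, 3] - d0[, 3] * u1[, 2],
                  d0[, 3] * u1[, 1] - d0[, 1] * u1[, 3],
                  d0[, 1] * u1[, 2] - d0[, 2] * u1[, 1])
      dir[is_in, ] <- d0 * cth + (u1 * cos(phi) + u2 * sin(phi)) * sth
      E[is_in] <- E[is_in] * x
    }
    # coherent scatter is strongly forward at these energies: keep direction
    # (transparent approximation; the package samples a narrow forward peak)

    # photoelectric: absorbed (energy transfer already scored via ftr)
    dead <- is_pe | E < cutoff
    keep <- !dead
    E <- E[keep]; pos <- pos[keep, , drop = FALSE]
    dir <- dir[keep, , drop = FALSE]
  }

  vol <- 4 / 3 * pi * diff(shells^3)
  tibble::tibble(
    r_cm = (shells[-1] + shells[-length(shells)]) / 2,
    dose = tall / vol / n
  )
}
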