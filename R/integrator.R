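# Embedded adaptive explicit Runge-Kutta 4(5) integration (Dormand-Prince)
# with the standard fourth-order continuous (dense) output interpolant and
# proportional step-size control.
#
# The stepper is owned by the package because the model's valve laws switch
# branches pointwise inside the right-hand side (no event localisation):
# robust behaviour of the error control around those derivative
# discontinuities -- rejected steps shrinking onto the switch so that the
# post-closure flow overshoot stays at the tolerance level -- is part of the
# simulation contract, and is verified directly by the test suite.

# Butcher tableau, Dormand & Prince 5(4), 7 stages, FSAL.
.dp_c <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
.dp_a <- list(
  NULL,
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
.dp_b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)
# dense-output weights (Hairer-Norsett-Wanner DOPRI5 continuous extension)
.dp_d <- c(-12715105075 / 11282082432, 0, 87487479700 / 32700410799,
           -10690763975 / 1880347072, 701980252875 / 199316789632,
           -1453857185 / 822651844, 69997945 / 29380423)

# Integrate dy/dt = rhs(t, y) from 0 to max(times), sampling the dense
# solution at `times` (sorted, times[1] == 0). Returns list(y = matrix
# [length(times) x n], steps_accepted, steps_rejected, fevals).
.integrate_dp45 <- function(rhs, y0, times, atol, rtol, max_steps,
                            h_init = 1e-4) {
  n <- length(y0)
  t_end <- times[length(times)]
  ygrid <- matrix(NA_real_, nrow = length(times), ncol = n)
  ygrid[1, ] <- y0
  next_out <- 2L

  t <- 0
  y <- y0
  h <- h_init
  k1 <- rhs(t, y)
  fevals <- 1L
  accepted <- 0L
  rejected <- 0L
  k <- vector("list", 7)

  while (t < t_end) {
    if (accepted + rejected >= max_steps) {
      stop(sprintf(paste0("step budget (%d) exhausted at t = %.6g s; ",
                          "last state: %s"),
           max_steps, t, paste(signif(y, 6), collapse = ", ")),
           call. = FALSE)
    }
    h <- min(h, t_end - t)
    k[[1]] <- k1
    for (i in 2:7) {
      a <- .dp_a[[i]]
      dy <- a[1] * k[[1]]
      if (i > 2) {
        for (j in 2:(i - 1)) {
          if (a[j] != 0) dy <- dy + a[j] * k[[j]]
        }
      }
      k[[i]] <- rhs(t + .dp_c[i] * h, y + h * dy)
    }
    fevals <- fevals + 6L
    inc5 <- .dp_b5[1] * k[[1]]
    inc4 <- .dp_b4[1] * k[[1]]
    for (i in 3:7) {
      inc5 <- inc5 + .dp_b5[i] * k[[i]]
      inc4 <- inc4 + .dp_b4[i] * k[[i]]
    }
    y_new <- y + h * inc5
    sc <- atol + rtol * pmax(abs(y), abs(y_new))
    err <- sqrt(mean(((h * (inc5 - inc4)) / sc)^2))
    if (!is.finite(err)) err <- Inf  # reject and shrink hard

    if (err <= 1) {
      # dense output on the passed interval before advancing
      while (next_out <= length(times) && times[next_out] <= t + h) {
        th <- (times[next_out] - t) / h
        dv <- .dp_d[1] * k[[1]]
        for (i in 3:7) dv <- dv + .dp_d[i] * k[[i]]
        bdiff <- y_new - y
        r3 <- h * k[[1]] - bdiff
        r4 <- bdiff - h * k[[7]] - r3
        r5 <- h * dv
        ygrid[next_out, ] <- y + th * (bdiff + (1 - th) *
                                         (r3 + th * (r4 + (1 - th) * r5)))
        next_out <- next_out + 1L
      }
      t <- t + h
      y <- y_new
      k1 <- k[[7]]  # FSAL: last stage is the first stage of the next step
      accepted <- accepted + 1L
      h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
    } else {
      rejected <- rejected + 1L
      h <- h * max(0.2, 0.9 * err^(-0.2))
      if (h < 1e-14) {
        stop(sprintf("step size underflow at t = %.6g s", t), call. = FALSE)
      }
    }
  }
  # outputs at (or within roundoff of) t_end not reached by dense output
  while (next_out <= length(times)) {
    ygrid[next_out, ] <- y
    next_out <- next_out + 1L
  }
  list(y = ygrid, steps_accepted = accepted, steps_rejected = rejected,
       fevals = fevals)
}
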