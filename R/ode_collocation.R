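# Hermite-Simpson transcription for small generic ODE systems. The gait
# problem runs through the compiled path; this light R path exercises the same
# discretization on problems with known solutions (order-of-accuracy and
# analytic optimal-control checks) and is handy for prototyping.

#' Describe a small optimal-control test problem
#'
#' @param f dynamics `function(t, x, u)` returning dx/dt.
#' @param nx,nu state and control dimensions (`nu = 0` for pure integration).
#' @param tf fixed final time.
#' @param x0 initial state (fixed); `xf` optional fixed final state.
#' @param lagrange running cost `function(t, x, u)` (default 0).
#' @param u_lb,u_ub optional control bounds.
#' @return an `ode_problem` object usable with [transcribe()].
#' @export
ode_problem <- function(f, nx, nu = 0L, tf, x0, xf = NULL,
                        lagrange = NULL, u_lb = -Inf, u_ub = Inf) {
  structure(list(f = f, nx = nx, nu = nu, tf = tf, x0 = x0, xf = xf,
                 lagrange = lagrange, u_lb = u_lb, u_ub = u_ub),
            class = "ode_problem")
}

hs_defects_ode <- function(prob, X, U, n) {
  h <- prob$tf / (n - 1)
  tt <- seq(0, prob$tf, length.out = n)
  F <- matrix(0, prob$nx, n)
  for (k in seq_len(n))
    F[, k] <- prob$f(tt[k], X[, k], if (prob$nu) U[, k] else numeric(0))
  d <- matrix(0, prob$nx, n - 1)
  for (k in seq_len(n - 1)) {
    xm <- 0.5 * (X[, k] + X[, k + 1]) + h / 8 * (F[, k] - F[, k + 1])
    um <- if (prob$nu) 0.5 * (U[, k] + U[, k + 1]) else numeric(0)
    fm <- prob$f(tt[k] + h / 2, xm, um)
    d[, k] <- X[, k + 1] - X[, k] - h / 6 * (F[, k] + 4 * fm + F[, k + 1])
  }
  d
}

#' @rdname transcribe
#' @export
transcribe.ode_problem <- function(model, grid = collocation_grid(21L), ...) {
  prob <- model
  n <- grid$n_nodes
  structure(list(prob = prob, n = n), class = "ode_nlp")
}

#' Solve a transcribed small ODE problem
#'
#' Defect and boundary constraints are handled with the same
#' augmented-Lagrangian scheme as the gait problem; gradients are plain
#' forward differences (the problems are tiny).
#'
#' @param nlp an `ode_nlp` from [transcribe()] on an [ode_problem()].
#' @param guess optional list with `X` (nx x n) and `U` (nu x n).
#' @param control a [solver_control()].
#' @return list with `X`, `U`, `times`, `objective`, `max_violation`,
#'   `converged`.
#' @export
solve_ode_nlp <- function(nlp, guess = NULL, control = solver_control(tol = 1e-7,
                                                                      mu0 = 10)) {
  prob <- nlp$prob; n <- nlp$n
  nx <- prob$nx; nu <- prob$nu
  tt <- seq(0, prob$tf, length.out = n)
  if (is.null(guess)) {
    X <- matrix(rep(prob$x0, n), nx, n)
    if (!is.null(prob$xf))
      for (i in seq_len(nx)) X[i, ] <- seq(prob$x0[i], prob$xf[i], length.out = n)
    U <- matrix(0, max(nu, 0), n)
  } else { X <- guess$X; U <- guess$U }
  pack <- function(X, U) c(as.vector(X), if (nu) as.vector(U) else NULL)
  unpack <- function(z) {
    X <- matrix(z[seq_len(nx * n)], nx, n)
    U <- if (nu) matrix(z[nx * n + seq_len(nu * n)], nu, n) else matrix(0, 0, n)
    list(X = X, U = U)
  }
  cons <- function(z) {
    s <- unpack(z)
    c(as.vector(hs_defects_ode(prob, s$X, s$U, n)),
      s$X[, 1] - prob$x0,
      if (!is.null(prob$xf)) s$X[, n] - prob$xf else NULL)
  }
  objf <- function(z) {
    if (is.null(prob$lagrange)) return(0)
    s <- unpack(z)
    h <- prob$tf / (n - 1)
    acc <- 0
    for (k in seq_len(n - 1)) {
      u0 <- if (nu) s$U[, k] else numeric(0)
      u1 <- if (nu) s$U[, k + 1] else numeric(0)
      g0 <- prob$lagrange(tt[k], s$X[, k], u0)
      g1 <- prob$lagrange(tt[k + 1], s$X[, k + 1], u1)
      gm <- prob$lagrange(tt[k] + h / 2, (s$X[, k] + s$X[, k + 1]) / 2,
                          (u0 + u1) / 2)
      acc <- acc + h / 6 * (g0 + 4 * gm + g1)
    }
    acc
  }
  lb <- c(rep(-Inf, nx * n), if (nu) rep(prob$u_lb, nu * n) else NULL)
  ub <- c(rep(Inf, nx * n), if (nu) rep(prob$u_ub, nu * n) else NULL)
  z <- pack(X, U)
  m <- length(cons(z))
  nz <- length(z)
  lambda <- numeric(m); mu <- control$mu0
  eps <- 1e-7
  fd_jac <- function(z, c0) {
    J <- matrix(0, m, nz)
    for (i in seq_len(nz)) {
      zp <- z; zp[i] <- zp[i] + eps
      J[, i] <- (cons(zp) - c0) / eps
    }
    J
  }
  fd_gobj <- function(z, f0) {
    g <- numeric(nz)
    for (i in seq_len(nz)) {
      zp <- z; zp[i] <- zp[i] + eps
      g[i] <- (objf(zp) - f0) / eps
    }
    g
  }
  phi <- function(z) {
    cc <- cons(z)
    objf(z) + sum(lambda * cc) + 0.5 * mu * sum(cc^2)
  }
  converged <- FALSE
  for (outer in seq_len(control$outer_max)) {
    # damped dense Gauss-Newton on the augmented Lagrangian
    lm <- 1e-6
    for (it in seq_len(60)) {
      c0 <- cons(z)
      J <- fd_jac(z, c0)
      g <- fd_gobj(z, objf(z)) + as.numeric(crossprod(J, lambda + mu * c0))
      H <- mu * crossprod(J)
      phi0 <- phi(z)
      step_ok <- FALSE
      for (try in 1:8) {
        p_step <- tryCatch(
          solve(H + diag(lm * (diag(H) + 1), nz), -g),
          error = function(e) NULL)
        if (!is.null(p_step)) {
          alpha <- 1
          for (ls in 1:8) {
            zn <- pmin(pmax(z + alpha * p_step, lb), ub)
            if (is.finite(phi(zn)) && phi(zn) < phi0 - 1e-14 * abs(phi0)) {
              z <- zn; step_ok <- TRUE; break
            }
            alpha <- alpha / 3
          }
        }
        if (step_ok) { lm <- max(lm / 3, 1e-9); break }
        lm <- lm * 10
        if (lm > 1e8) break
      }
      if (!step_ok) break
      if (phi0 - phi(z) < 1e-12 * (1 + abs(phi0))) break
    }
    cc <- cons(z)
    viol <- max(abs(cc))
    lambda <- lambda + mu * cc
    if (viol <= control$tol) { converged <- TRUE; break }
    mu <- mu * control$mu_mult
  }
  s <- unpack(z)
  list(X = s$X, U = s$U, times = tt, objective = objf(z),
       max_violation = max(abs(cons(z))), converged = converged)
}

#' Implicit Hermite-Simpson integration of an ODE
#'
#' Steps through the grid solving each interval's compressed Hermite-Simpson
#' defect for the next state by Newton iteration; the discrete solution is
#' identical to the collocation defect constraints being satisfied exactly,
#' so its error against a known solution exhibits the transcription's order.
#'
#' @param f dynamics `function(t, x)`.
#' @param x0 initial state.
#' @param tf final time; `n` node count.
#' @return matrix nx x n of states at the nodes.
#' @export
hs_integrate <- function(f, x0, tf, n) {
  nx <- length(x0)
  h <- tf / (n - 1)
  tt <- seq(0, tf, length.out = n)
  X <- matrix(0, nx, n)
  X[, 1] <- x0
  for (k in seq_len(n - 1)) {
    xk <- X[, k]
    fk <- f(tt[k], xk)
    g <- function(xn) {
      fn <- f(tt[k + 1], xn)
      xm <- 0.5 * (xk + xn) + h / 8 * (fk - fn)
      fm <- f(tt[k] + h / 2, xm)
      xn - xk - h / 6 * (fk + 4 * fm + fn)
    }
    xn <- xk + h * fk  # explicit Euler predictor
    for (it in 1:20) {
      r <- g(xn)
      if (max(abs(r)) < 1e-13) break
      J <- matrix(0, nx, nx); eps <- 1e-8
      for (j in seq_len(nx)) {
        xp <- xn; xp[j] <- xp[j] + eps
        J[, j] <- (g(xp) - r) / eps
      }
      xn <- xn - solve(J, r)
    }
    X[, k + 1] <- xn
  }
  X
}
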