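# Hand-written complex Krylov solvers. Everything works on closures:
# `matvec(v)` applies the operator, `prec(v)` applies the (right)
# preconditioner M^{-1}. Residuals are relative to ||b||.

cnorm <- function(x) sqrt(sum(Mod(x)^2))
cdot <- function(x, y) sum(Conj(x) * y)

# Restarted right-preconditioned GMRES; `flexible = TRUE` gives FGMRES
# (the preconditioned vectors are stored, allowing a varying preconditioner).
gmres_c <- function(matvec, b, prec = identity, tol = 1e-6,
                    maxit = 1000L, restart = 50L, flexible = FALSE) {
  n <- length(b)
  bnorm <- cnorm(b)
  if (bnorm == 0) {
    return(list(x = complex(n), iterations = 0L, residual = 0,
                history = numeric(0), converged = TRUE))
  }
  x <- complex(n)
  iters <- 0L
  history <- numeric(0)
  repeat {
    r <- b - matvec(x)
    beta <- cnorm(r)
    if (beta / bnorm <= tol || iters >= maxit) break
    m <- min(restart, maxit - iters)
    V <- matrix(0i, n, m + 1L)
    Z <- if (flexible) matrix(0i, n, m) else NULL
    H <- matrix(0i, m + 1L, m)
    V[, 1] <- r / beta
    j_used <- 0L
    rhs <- c(beta, complex(m))
    for (j in seq_len(m)) {
      z <- prec(V[, j])
      if (flexible) Z[, j] <- z
      w <- matvec(z)
      for (i2 in seq_len(j)) {              # modified Gram-Schmidt
        H[i2, j] <- cdot(V[, i2], w)
        w <- w - H[i2, j] * V[, i2]
      }
      H[j + 1L, j] <- cnorm(w)
      j_used <- j
      iters <- iters + 1L
      Hj <- H[seq_len(j + 1L), seq_len(j), drop = FALSE]
      y <- qr.solve(Hj, rhs[seq_len(j + 1L)])
      res <- cnorm(rhs[seq_len(j + 1L)] - Hj %*% y) / bnorm
      history <- c(history, res)
      if (Mod(H[j + 1L, j]) < 1e-14 * bnorm) break      # lucky breakdown
      V[, j + 1L] <- w / H[j + 1L, j]
      if (res <= tol || iters >= maxit) break
    }
    Hj <- H[seq_len(j_used + 1L), seq_len(j_used), drop = FALSE]
    y <- qr.solve(Hj, rhs[seq_len(j_used + 1L)])
    if (flexible) {
      x <- x + as.vector(Z[, seq_len(j_used), drop = FALSE] %*% y)
    } else {
      x <- x + prec(as.vector(V[, seq_len(j_used), drop = FALSE] %*% y))
    }
  }
  res <- cnorm(b - matvec(x)) / bnorm
  list(x = x, iterations = iters, residual = res, history = history,
       converged = res <= tol)
}

# Right-preconditioned BiCGStab.
bicgstab_c <- function(matvec, b, prec = identity, tol = 1e-6,
                       maxit = 1000L) {
  n <- length(b)
  bnorm <- cnorm(b)
  if (bnorm == 0) {
    return(list(x = complex(n), iterations = 0L, residual = 0,
                history = numeric(0), converged = TRUE))
  }
  x <- complex(n)
  r <- b
  r0 <- r
  rho <- alpha <- omega <- 1 + 0i
  v <- p <- complex(n)
  history <- numeric(0)
  iters <- 0L
  while (iters < maxit) {
    rho1 <- cdot(r0, r)
    if (Mod(rho1) < 1e-300) break                       # breakdown
    if (iters == 0L) {
      p <- r
    } else {
      beta <- (rho1 / rho) * (alpha / omega)
      p <- r + beta * (p - omega * v)
    }
    ph <- prec(p)
    v <- matvec(ph)
    alpha <- rho1 / cdot(r0, v)
    s <- r - alpha * v
    if (cnorm(s) / bnorm <= tol) {
      x <- x + alpha * ph
      iters <- iters + 1L
      history <- c(history, cnorm(s) / bnorm)
      break
    }
    sh <- prec(s)
    t <- matvec(sh)
    omega <- cdot(t, s) / cdot(t, t)
    x <- x + alpha * ph + omega * sh
    r <- s - omega * t
    rho <- rho1
    iters <- iters + 1L
    res <- cnorm(r) / bnorm
    history <- c(history, res)
    if (res <= tol) break
    if (Mod(omega) < 1e-300) break
  }
  res <- cnorm(b - matvec(x)) / bnorm
  list(x = x, iterations = iters, residual = res, history = history,
       converged = res <= tol)
}
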