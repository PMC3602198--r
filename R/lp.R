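#' Solve a bounded-variable linear program
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `A x = b` and
#' `lb <= x <= ub`, using a dense two-phase primal simplex with
#' bounded-variable pivoting. This is the linear-programming core behind all
#' flux-balance computations in the package: the flux vector is the
#' variable, the stoichiometric matrix supplies the equality rows, and the
#' flux bounds enter natively (no slack inflation).
#'
#' Phase 1 drives artificial variables out of the basis to find a feasible
#' vertex; phase 2 optimizes the true objective. Entering variables are
#' priced by the Dantzig rule, switching to Bland's rule (which cannot
#' cycle) after a fixed iteration budget. The basis system is re-solved from
#' scratch at every iteration, trading speed for numerical robustness on the
#' heavily degenerate LPs that metabolic models produce.
#'
#' @param A Dense numeric constraint matrix (m x n).
#' @param b Right-hand side (length m).
#' @param lb,ub Variable bounds (length n); `ub` may contain `Inf`, `lb`
#'   may contain `-Inf`, but not both for the same variable.
#' @param obj Objective coefficients (length n).
#' @param sense `"max"` or `"min"`.
#' @param tol Optimality tolerance on reduced costs.
#' @param ftol Primal feasibility tolerance (phase-1 residual).
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), `objective` and `x` (length n; `NA` unless optimal).
#' @export
solve_lp <- function(A, b, lb, ub, obj, sense = c("max", "min"),
                     tol = 1e-9, ftol = 1e-7) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(lb) == n, length(ub) == n,
            length(obj) == n)
  if (any(lb > ub)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  if (any(is.infinite(lb) & is.infinite(ub))) {
    stop("variables free on both sides are not supported", call. = FALSE)
  }
  cvec <- if (sense == "min") -obj else obj

  # initial nonbasic values: the finite bound of smaller magnitude
  start_at_lb <- is.finite(lb) & (!is.finite(ub) | abs(lb) <= abs(ub))
  status <- ifelse(start_at_lb, 1L, 2L)   # 1 = at lb, 2 = at ub
  xval <- ifelse(status == 1L, lb, ub)

  r <- b - as.vector(A %*% xval)
  sg <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sg, m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  N <- n + m
  basis <- (n + 1L):N
  stat <- c(status, rep(0L, m))           # 0 = basic
  run_simplex <- function(cost, basis, stat, phase, itbudget, bland_after) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > itbudget) {
        return(list(status = "maxiter", basis = basis, stat = stat))
      }
      nonbasic <- which(stat != 0L)
      xNv <- ifelse(stat[nonbasic] == 1L, lbf[nonbasic], ubf[nonbasic])
      Bmat <- Afull[, basis, drop = FALSE]
      rhs <- b - as.vector(Afull[, nonbasic, drop = FALSE] %*% xNv)
      xB <- tryCatch(solve(Bmat, rhs), error = function(e) NULL)
      y <- tryCatch(solve(t(Bmat), cost[basis]), error = function(e) NULL)
      if (is.null(xB) || is.null(y)) {
        return(list(status = "singular", basis = basis, stat = stat))
      }
      d <- cost[nonbasic] - as.vector(crossprod(Afull[, nonbasic, drop = FALSE], y))
      up_ok <- stat[nonbasic] == 1L & d > tol
      dn_ok <- stat[nonbasic] == 2L & d < -tol
      elig <- up_ok | dn_ok
      if (!any(elig)) {
        return(list(status = "optimal", basis = basis, stat = stat,
                    xB = xB, nonbasic = nonbasic, xNv = xNv))
      }
      cand <- which(elig)
      q_rel <- if (it > bland_after) {
        cand[which.min(nonbasic[cand])]            # Bland
      } else {
        cand[which.max(abs(d[cand]))]              # Dantzig
      }
      q <- nonbasic[q_rel]
      dir <- if (stat[q] == 1L) 1 else -1
      w <- solve(Bmat, Afull[, q])
      delta <- -dir * w
      # ratio test: step limited by the entering span (bound flip) or by
      # the first basic variable hitting one of its bounds
      tmax <- if (is.finite(ubf[q]) && is.finite(lbf[q])) ubf[q] - lbf[q] else Inf
      limit <- "flip"
      leave <- NA_integer_
      leave_hit <- NA_integer_
      ptol <- 1e-10
      for (i in seq_len(m)) {
        if (delta[i] < -ptol) {
          ti <- (xB[i] - lbf[basis[i]]) / (-delta[i])
          hit <- 1L
        } else if (delta[i] > ptol) {
          ti <- (ubf[basis[i]] - xB[i]) / delta[i]
          hit <- 2L
        } else next
        if (ti < 0) ti <- 0   # degenerate: clamp slightly-negative ratios
        take <- if (ti < tmax - 1e-12) {
          TRUE
        } else if (abs(ti - tmax) <= 1e-12 && limit == "basic" &&
                   abs(delta[i]) > abs(delta[leave])) {
          TRUE   # tie: prefer the larger pivot for stability
        } else {
          FALSE
        }
        if (take) {
          tmax <- ti
          limit <- "basic"
          leave <- i
          leave_hit <- hit
        }
      }
      if (!is.finite(tmax)) {
        return(list(status = "unbounded", basis = basis, stat = stat))
      }
      if (limit == "flip") {
        stat[q] <- if (stat[q] == 1L) 2L else 1L
      } else {
        out <- basis[leave]
        stat[out] <- leave_hit
        stat[q] <- 0L
        basis[leave] <- q
      }
    }
  }

  budget <- max(200L, 60L * N)
  bland_after <- max(50L, 10L * N)

  # phase 1: maximize -sum(artificials)
  c1 <- c(rep(0, n), rep(-1, m))
  res1 <- run_simplex(c1, basis, stat, 1L, budget, bland_after)
  if (res1$status != "optimal") {
    st <- if (res1$status %in% c("singular", "maxiter")) "maxiter" else res1$status
    return(list(status = st, objective = NA_real_, x = rep(NA_real_, n)))
  }
  x1 <- lp_extract(res1, lbf, ubf, N)
  if (sum(x1[(n + 1L):N]) > ftol) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  # phase 2: lock artificials at zero, optimize true objective
  ubf[(n + 1L):N] <- 0
  lbf[(n + 1L):N] <- 0
  c2 <- c(cvec, rep(0, m))
  res2 <- run_simplex(c2, res1$basis, res1$stat, 2L, budget, bland_after)
  if (res2$status != "optimal") {
    st <- if (res2$status %in% c("singular", "maxiter")) "maxiter" else res2$status
    return(list(status = st, objective = NA_real_, x = rep(NA_real_, n)))
  }
  xfull <- lp_extract(res2, lbf, ubf, N)
  x <- xfull[seq_len(n)]
  objective <- sum(obj * x)
  list(status = "optimal", objective = objective, x = x)
}

lp_extract <- function(res, lbf, ubf, N) {
  x <- numeric(N)
  nb <- which(res$stat != 0L)
  x[nb] <- ifelse(res$stat[nb] == 1L, lbf[nb], ubf[nb])
  x[res$basis] <- res$xB
  x
}
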