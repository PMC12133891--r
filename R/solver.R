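#' Solver settings for flux balance computations
#'
#' @param norm `"L2"` (protocol: minimize the Euclidean norm, i.e. the sum
#'   of squared fluxes across all reactions) or `"L1"` (classic
#'   minimal-total-flux parsimonious FBA, offered as a fallback; results are
#'   flagged as non-protocol).
#' @param feasibility_tol Tolerance on bound violations.
#' @param optimality_tol Solver optimality tolerance.
#' @param mass_balance_tol Tolerance on the steady-state residual
#'   `max |S v|` (relative to `max(1, max |v|)`).
#' @param maintenance_value Value the whole-body maintenance flux is pinned
#'   to before solving (both bounds set to this value; default 1).
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(norm = c("L2", "L1"),
                            feasibility_tol = 1e-8,
                            optimality_tol = 1e-8,
                            mass_balance_tol = 1e-6,
                            maintenance_value = 1.0) {
  norm <- match.arg(norm)
  stopifnot(feasibility_tol > 0, optimality_tol > 0, mass_balance_tol > 0,
            is.finite(maintenance_value))
  structure(list(norm = norm, feasibility_tol = feasibility_tol,
                 optimality_tol = optimality_tol,
                 mass_balance_tol = mass_balance_tol,
                 maintenance_value = maintenance_value),
            class = "solver_settings")
}

new_flux_solution <- function(model, v, status, objective = NA_real_,
                              backend = NA_character_, norm = "L2") {
  rx <- model$reactions
  fluxes <- if (is.null(v)) {
    tibble(reaction_id = character(), flux = numeric())
  } else {
    tibble(reaction_id = rx$id, flux = as.numeric(v))
  }
  res <- bound_viol <- NA_real_
  if (!is.null(v)) {
    S <- stoich_matrix(model)
    res <- max(abs(as.numeric(S %*% v)), 0)
    bound_viol <- max(c(rx$lb - v, v - rx$ub, 0))
  }
  structure(
    list(fluxes = fluxes, objective = objective, status = status,
         max_mass_balance_residual = res, max_bound_violation = bound_viol,
         backend = backend, norm = norm, model_id = model$model_id,
         sex = model$sex),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> %s [%s, %s norm] status=%s\n",
              x$model_id, x$backend, x$norm, x$status))
  if (x$status == "optimal") {
    cat(sprintf("  objective %.6g | max |S v| %.3g | max bound violation %.3g\n",
                x$objective, x$max_mass_balance_residual, x$max_bound_violation))
  }
  invisible(x)
}

# Pin the maintenance reaction and return (bounds-updated reactions, S).
prepare_problem <- function(model, settings) {
  rx <- model$reactions
  i <- match(model$maintenance_id, rx$id)
  rx$lb[i] <- settings$maintenance_value
  rx$ub[i] <- settings$maintenance_value
  list(rx = rx, S = stoich_matrix(model))
}

# Indices of a maximal linearly independent subset of the rows of S.
independent_rows <- function(S) {
  Sd <- as.matrix(S)
  if (nrow(Sd) == 0) return(integer())
  qrd <- qr(t(Sd))
  sort(qrd$pivot[seq_len(qrd$rank)])
}

#' Parsimonious flux balance analysis (minimum Euclidean norm)
#'
#' Computes the flux distribution `v` minimizing the sum of squared fluxes
#' over *all* reactions (exchange and maintenance reactions included; the
#' pinned maintenance flux contributes a constant), subject to steady-state
#' mass balance `S v = 0` and the bound constraints `lb <= v <= ub`. The
#' whole-body maintenance reaction is pinned to
#' `settings$maintenance_value` by setting both of its bounds before
#' solving. Because the objective is strictly convex and the feasible set
#' convex, the optimum is unique.
#'
#' Two backends are available: `"quadprog"` (Goldfarb–Idnani dual
#' active-set method) and `"dual"`, an independent implementation using
#' dual ascent on the mass-balance multipliers followed by a primal-dual
#' active-set polish. They agree to high precision and serve as mutual
#' cross-checks. With `settings$norm = "L1"` a minimal-total-flux linear
#' program is solved instead (positive/negative flux splitting) and the
#' result is flagged as non-protocol.
#'
#' @param model A validated [wbm()] model.
#' @param settings A [solver_settings()].
#' @param backend `"quadprog"` or `"dual"`.
#' @return A `flux_solution`: tidy flux table plus `objective`, `status`
#'   (`optimal`, `infeasible`, `unbounded`, `numeric_failure`) and residual
#'   diagnostics.
#' @examples
#' toy <- make_toy_wbm(organs = "Liver", options = list(chain_only = TRUE))
#' sol <- pfba(toy$model)
#' tidy(sol)
#' @export
pfba <- function(model, settings = solver_settings(),
                 backend = c("quadprog", "dual")) {
  backend <- match.arg(backend)
  if (settings$norm == "L1") {
    return(pfba_l1(model, settings))
  }
  prob <- prepare_problem(model, settings)
  rx <- prob$rx
  if (any(rx$lb > rx$ub + settings$feasibility_tol)) {
    return(new_flux_solution(model, NULL, "infeasible", backend = backend))
  }
  S <- prob$S
  keep <- independent_rows(S)
  Sr <- as.matrix(S[keep, , drop = FALSE])
  v <- switch(backend,
    quadprog = qp_quadprog(Sr, rx$lb, rx$ub),
    dual = qp_dual(Sr, rx$lb, rx$ub)
  )
  if (is.null(v) && backend == "quadprog") {
    # all active-set attempts failed; the dual-ascent backend is the
    # deterministic fallback and is recorded as such
    v <- qp_dual(Sr, rx$lb, rx$ub)
    if (!is.null(v)) backend <- "dual"
  }
  if (is.null(v)) {
    # distinguish genuine infeasibility from numeric failure with a slack LP
    feas <- feasibility_gap(model, settings)
    status <- if (!is.na(feas) && feas > settings$feasibility_tol) "infeasible"
              else "numeric_failure"
    return(new_flux_solution(model, NULL, status, backend = backend))
  }
  sol <- new_flux_solution(model, v, "optimal", objective = sum(v^2),
                           backend = backend)
  scale <- max(1, max(abs(v)))
  if (sol$max_mass_balance_residual > settings$mass_balance_tol * scale ||
      sol$max_bound_violation > 1e2 * settings$feasibility_tol) {
    sol$status <- "numeric_failure"
  }
  sol
}

# Goldfarb-Idnani backend for  min 1/2||v||^2 - d'v  s.t.  Sr v = b, box.
qp_quadprog <- function(Sr, lb, ub, d = NULL, b = NULL) {
  n <- length(lb)
  m <- nrow(Sr)
  d <- d %||% rep(0, n)
  b <- b %||% rep(0, m)
  # two scalings of the equality rows: the Goldfarb-Idnani active-set
  # method is exact but its pivoting is sensitive to row scaling when
  # sentinel big-M bounds mix with tight physiological bounds, and neither
  # scaling dominates; results are verified downstream either way
  rn <- if (m) sqrt(rowSums(Sr^2)) else numeric()
  solve_with <- function(normalize, lo_idx, hi_idx) {
    Se <- Sr; be <- b
    if (normalize && m) { Se <- Sr / rn; be <- b / rn }
    Amat <- cbind(t(Se), diag(n)[, lo_idx, drop = FALSE],
                  -diag(n)[, hi_idx, drop = FALSE])
    bvec <- c(be, lb[lo_idx], -ub[hi_idx])
    tryCatch(
      quadprog::solve.QP(Dmat = diag(n), dvec = d,
                         Amat = Amat, bvec = bvec, meq = m)$solution,
      error = function(e) NULL)
  }
  all_i <- seq_len(n)
  lo <- which(lb > -1e5); hi <- which(ub < 1e5)
  for (attempt in list(list(FALSE, all_i, all_i), list(TRUE, all_i, all_i),
                       list(TRUE, lo, hi), list(FALSE, lo, hi))) {
    v <- solve_with(attempt[[1]], attempt[[2]], attempt[[3]])
    if (!is.null(v) && all(v >= lb - 1e-8) && all(v <= ub + 1e-8)) return(v)
  }
  NULL
}

# Independent QP backend: maximize the dual of
#   min 1/2 ||v||^2 - d'v  s.t.  S v = b, lb <= v <= ub
# over the mass-balance multipliers lambda; v(lambda) = clamp(d - S'lambda).
# The smooth dual is maximized with L-BFGS-B, then the implied active set is
# refined with a primal-dual active-set iteration solved through the normal
# equations of the free block.
qp_dual <- function(Sr, lb, ub, d = NULL, b = NULL, max_polish = 60) {
  m <- nrow(Sr); n <- ncol(Sr)
  d <- d %||% rep(0, n)
  b <- b %||% rep(0, m)
  if (m == 0) return(pmin(pmax(d, lb), ub))
  clampv <- function(lam) {
    pmin(pmax(d - as.numeric(crossprod(Sr, lam)), lb), ub)
  }
  negdual <- function(lam) {
    # g = 1/2||v||^2 - v'y - lam'b with v = clamp(y), y = d - S'lam; -g
    y <- d - as.numeric(crossprod(Sr, lam))
    v <- pmin(pmax(y, lb), ub)
    sum(v * y) - 0.5 * sum(v^2) + sum(lam * b)
  }
  neggrad <- function(lam) -(as.numeric(Sr %*% clampv(lam)) - b)
  fit <- tryCatch(
    stats::optim(rep(0, m), negdual, neggrad, method = "L-BFGS-B",
                 control = list(maxit = 2000, factr = 1e4)),
    error = function(e) list(par = rep(0, m)))
  lam <- fit$par
  v <- clampv(lam)

  # primal-dual active-set polish
  tol <- 1e-9
  state <- integer(n)  # 0 free, -1 at lb, +1 at ub, 2 pinned
  state[abs(v - lb) < 1e-7] <- -1L
  state[abs(v - ub) < 1e-7] <- 1L
  state[lb == ub] <- 2L
  best <- v
  for (iter in seq_len(max_polish)) {
    act <- state != 0L
    vA <- ifelse(state == 1L, ub, lb)  # value when active (pinned: lb == ub)
    bb <- b - if (any(act))
      as.numeric(Sr[, act, drop = FALSE] %*% vA[act]) else rep(0, m)
    SF <- Sr[, !act, drop = FALSE]
    vtry <- numeric(n)
    if (ncol(SF) == 0) {
      vtry <- vA
      # least-squares multipliers from stationarity over the active set
      lam2 <- tryCatch(qr.coef(qr(t(Sr)), d - vtry), error = function(e) rep(0, m))
      lam2[is.na(lam2)] <- 0
      lam2 <- matrix(lam2, ncol = 1)
    } else {
      sv <- svd(SF, nu = nrow(SF), nv = 0)
      pos <- sv$d > max(sv$d[1], 1) * 1e-12
      # KKT: v_F = d_F - S_F' lam and S_F v_F = bb
      #      =>  (S_F S_F') lam = S_F d_F - bb
      rhs <- as.numeric(SF %*% d[!act]) - bb
      Ur <- crossprod(sv$u, rhs)
      lam2 <- sv$u[, seq_along(sv$d), drop = FALSE][, pos, drop = FALSE] %*%
        (Ur[seq_along(sv$d)][pos] / sv$d[pos]^2)
      vF <- d[!act] - as.numeric(crossprod(SF, lam2))
      vtry[act] <- vA[act]; vtry[!act] <- vF
    }
    eq_res <- max(abs(as.numeric(Sr %*% vtry) - b))
    eq_ok <- eq_res <= 1e-7 * max(1, max(abs(vtry)))
    viol_lo <- !act & (vtry < lb - tol)
    viol_hi <- !act & (vtry > ub + tol)
    grad <- vtry - d + as.numeric(crossprod(Sr, lam2))  # stationarity residual
    rel_lo <- state == -1L & grad < -tol
    rel_hi <- state == 1L & grad > tol
    any_change <- any(viol_lo | viol_hi | rel_lo | rel_hi)
    if (eq_ok) best <- vtry
    if (eq_ok && !any_change) break     # KKT satisfied
    if (!any_change) break              # stuck: no update available
    state[viol_lo] <- -1L
    state[viol_hi] <- 1L
    state[rel_lo] <- 0L
    state[rel_hi] <- 0L
  }
  cand <- best
  objective <- function(x) 0.5 * sum(x^2) - sum(d * x)
  res_of <- function(x) max(abs(as.numeric(Sr %*% x) - b)) +
    max(c(lb - x, x - ub, 0))
  out <- if (res_of(cand) <= res_of(v) || objective(cand) <= objective(v))
    cand else v
  if (max(abs(as.numeric(Sr %*% out) - b)) > 1e-4 * max(1, max(abs(out)))) {
    return(NULL)
  }
  out
}

# Robust solve of  min 1/2||v||^2 - d'v  s.t.  A v = rhs, box: the
# Goldfarb-Idnani attempts first, the dual-ascent backend as fallback, and
# the result verified against residual and bound tolerances.
qp_box <- function(A, rhs, lb, ub, d = NULL) {
  v <- qp_quadprog(A, lb, ub, d = d, b = rhs)
  if (is.null(v)) v <- qp_dual(A, lb, ub, d = d, b = rhs)
  if (is.null(v)) return(NULL)
  if (max(abs(as.numeric(A %*% v) - rhs)) > 1e-6 * max(1, max(abs(v))) ||
      any(v < lb - 1e-6) || any(v > ub + 1e-6)) return(NULL)
  v
}

pfba_l1 <- function(model, settings) {
  prob <- prepare_problem(model, settings)
  rx <- prob$rx
  S <- as.matrix(prob$S)
  n <- nrow(rx)
  # v = p - q with p, q >= 0; minimize sum(p + q)
  lp <- lp_box(obj = rep(1, 2 * n),
               A_eq = cbind(S, -S),
               b_eq = rep(0, nrow(S)),
               lb = rep(0, 2 * n),
               ub = c(pmax(rx$ub, 0), pmax(-rx$lb, 0)),
               extra_geq = cbind(diag(n), -diag(n)),
               extra_geq_rhs = rx$lb,
               extra_leq = cbind(diag(n), -diag(n)),
               extra_leq_rhs = rx$ub,
               maximize = FALSE)
  if (lp$status != "optimal") {
    return(new_flux_solution(model, NULL, lp$status, backend = "simplex", norm = "L1"))
  }
  v <- lp$x[seq_len(n)] - lp$x[n + seq_len(n)]
  sol <- new_flux_solution(model, v, "optimal", objective = sum(abs(v)),
                           backend = "simplex", norm = "L1")
  sol
}

#' Flux balance analysis of a single objective reaction
#'
#' Linear-programming optimum of one reaction's flux subject to steady-state
#' mass balance and the model's bounds (maintenance bounds are *not* pinned;
#' the caller controls them). Used for feasibility probes and envelope
#' queries on toy-scale models.
#'
#' @param model A [wbm()] model.
#' @param objective_reaction Reaction id to optimize.
#' @param sense `"max"` or `"min"`.
#' @return A `flux_solution` whose `objective` is the optimal flux of the
#'   chosen reaction.
#' @export
fba <- function(model, objective_reaction, sense = c("max", "min")) {
  sense <- match.arg(sense)
  rx <- model$reactions
  j <- match(objective_reaction, rx$id)
  if (is.na(j)) {
    abort(paste0("Unknown objective reaction: ", objective_reaction),
          class = "dietwbm_integrity_error")
  }
  obj <- numeric(nrow(rx)); obj[j] <- 1
  lp <- lp_box(obj = obj, A_eq = as.matrix(stoich_matrix(model)),
               b_eq = rep(0, nrow(model$metabolites)),
               lb = rx$lb, ub = rx$ub, maximize = (sense == "max"))
  if (lp$status != "optimal") {
    return(new_flux_solution(model, NULL, lp$status, backend = "simplex", norm = "LP"))
  }
  new_flux_solution(model, lp$x, "optimal", objective = lp$x[j],
                    backend = "simplex", norm = "LP")
}

# Internal LP on a box-constrained flux polytope:
#   max/min obj'v  s.t.  A_eq v = b_eq, lb <= v <= ub,
# plus optional general inequality rows (converted to equalities with
# bounded slack variables). Solved through the quadratic regularization
# path: the minimizer of 1/2||x||^2 + t c'x over the polytope is piecewise
# linear in t and, beyond a finite threshold, equals the least-norm point
# of the LP optimal face. The substitution x = t z keeps every solve on
# the well-conditioned unit scale; t is increased along a ladder until the
# objective value stabilizes.
lp_box <- function(obj, A_eq, b_eq, lb, ub,
                   extra_geq = NULL, extra_geq_rhs = NULL,
                   extra_leq = NULL, extra_leq_rhs = NULL,
                   maximize = TRUE) {
  n <- length(obj)
  cc <- if (maximize) -obj else obj
  slack_cap <- 1e7
  A <- A_eq; rhs <- b_eq
  lb_a <- lb; ub_a <- ub; c_a <- cc
  if (!is.null(extra_geq)) {
    g <- nrow(extra_geq)
    A <- cbind(A, matrix(0, nrow(A), g))
    A <- rbind(A, cbind(extra_geq, -diag(g)))
    rhs <- c(rhs, extra_geq_rhs)
    lb_a <- c(lb_a, rep(0, g)); ub_a <- c(ub_a, rep(slack_cap, g))
    c_a <- c(c_a, rep(0, g))
  }
  if (!is.null(extra_leq)) {
    l <- nrow(extra_leq)
    A <- cbind(A, matrix(0, nrow(A), l))
    A <- rbind(A, cbind(extra_leq, matrix(0, l, ncol(A) - n - l), diag(l)))
    rhs <- c(rhs, extra_leq_rhs)
    lb_a <- c(lb_a, rep(0, l)); ub_a <- c(ub_a, rep(slack_cap, l))
    c_a <- c(c_a, rep(0, l))
  }
  keep <- independent_rows(A)
  A <- A[keep, , drop = FALSE]; rhs <- rhs[keep]

  prev_val <- NA_real_; x <- NULL
  for (t in 10^seq(3, 11, by = 2)) {
    z <- qp_box(A, rhs / t, lb_a / t, ub_a / t, d = -c_a)
    if (is.null(z)) next
    x_t <- t * z
    val <- sum(c_a * x_t)
    if (!is.na(prev_val) &&
        abs(val - prev_val) <= 1e-9 * max(1, abs(val))) {
      x <- x_t
      break
    }
    prev_val <- val; x <- x_t
  }
  if (is.null(x)) {
    feas <- qp_box(A, rhs, lb_a, ub_a)
    status <- if (is.null(feas)) "infeasible" else "numeric_failure"
    return(list(status = status, x = NULL, value = NA_real_))
  }
  if (any(abs(x[seq_len(n)]) > 1e5 & cc != 0)) {
    # the optimum rides a sentinel big-M bound in an objective variable
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  value <- sum(obj * x[seq_len(n)])
  list(status = "optimal", x = x[seq_len(n)], value = value)
}

# Minimal total slack (relative to diet-exchange and maintenance bounds)
# required to make the model feasible; 0 for feasible models, NA when even
# the fully relaxed problem is infeasible.
feasibility_gap <- function(model, settings = solver_settings()) {
  d <- diagnose_slack(model, settings)
  if (is.null(d)) return(NA_real_)
  d$total
}

#' Diagnose an infeasible model
#'
#' Solves a slack linear program: diet-exchange and maintenance bounds may
#' be relaxed (lower bounds down, upper bounds up) by non-negative slacks,
#' and the total slack is minimized. Nonzero slacks localize the bounds
#' whose relaxation restores feasibility, e.g. the minimum nutrient uptake
#' a closed diet must supply.
#'
#' @param model A [wbm()] model (typically one for which [pfba()] returned
#'   `infeasible`).
#' @param settings A [solver_settings()]; the maintenance pin is applied
#'   before diagnosis.
#' @return A tibble with columns `reaction_id`, `bound` (`"lb"`/`"ub"`),
#'   `relaxation`, sorted by decreasing relaxation; zero rows for feasible
#'   models.
#' @export
diagnose_infeasibility <- function(model, settings = solver_settings()) {
  d <- diagnose_slack(model, settings)
  if (is.null(d)) {
    abort("Slack relaxation problem is itself infeasible; model integrity is broken.",
          class = "dietwbm_model_error")
  }
  d$table
}

diagnose_slack <- function(model, settings) {
  prob <- prepare_problem(model, settings)
  rx <- prob$rx
  S <- as.matrix(prob$S)
  n <- nrow(rx)
  relax <- which(rx$kind %in% c("diet_exchange", "maintenance"))
  k <- length(relax)
  if (k == 0) return(list(total = NA_real_, table = NULL))
  # variables: v (n), s_lo (k), s_hi (k). The maintenance slack is heavily
  # penalized: the pinned maintenance flux is the protocol constant, so a
  # diagnosis should localize on dietary supply whenever relaxing a diet
  # bound can restore feasibility.
  w <- ifelse(rx$kind[relax] == "maintenance", 100, 1)
  nv <- n + 2 * k
  obj <- c(rep(0, n), w, w)
  A_eq <- cbind(S, matrix(0, nrow(S), 2 * k))
  lb_all <- c(rx$lb, rep(0, 2 * k))
  ub_all <- c(rx$ub, rep(1e5, 2 * k))
  # for relaxable i: v_i + s_lo_i >= lb_i  and  v_i - s_hi_i <= ub_i
  E <- matrix(0, k, nv); Eh <- matrix(0, k, nv)
  for (t in seq_len(k)) {
    i <- relax[t]
    E[t, i] <- 1; E[t, n + t] <- 1
    Eh[t, i] <- 1; Eh[t, n + k + t] <- -1
    lb_all[i] <- -1e5 - abs(rx$lb[i])   # hard box widened; slack rows bind
    ub_all[i] <- 1e5 + abs(rx$ub[i])
  }
  lp <- lp_box(obj = obj, A_eq = A_eq, b_eq = rep(0, nrow(S)),
               lb = lb_all, ub = ub_all,
               extra_geq = E, extra_geq_rhs = rx$lb[relax],
               extra_leq = Eh, extra_leq_rhs = rx$ub[relax],
               maximize = FALSE)
  if (lp$status != "optimal") return(NULL)
  s_lo <- lp$x[n + seq_len(k)]
  s_hi <- lp$x[n + k + seq_len(k)]
  tab <- bind_rows(
    tibble(reaction_id = rx$id[relax], bound = "lb", relaxation = pmax(s_lo, 0)),
    tibble(reaction_id = rx$id[relax], bound = "ub", relaxation = pmax(s_hi, 0))
  )
  tab <- tab[tab$relaxation > 1e-7, , drop = FALSE]
  tab <- arrange(tab, dplyr::desc(.data$relaxation))
  list(total = sum(tab$relaxation), table = tab)
}

#' Exhaustive QP oracle for small models
#'
#' Independent reference solver for the L2 parsimonious FBA problem: it
#' enumerates every assignment of bound-activity states (free, at lower
#' bound, at upper bound) over the reactions, solves each resulting
#' equality-constrained least-norm problem by singular value decomposition,
#' and returns the feasible candidate of smallest objective. Exponential in
#' the reaction count; refused above 12 reactions. Used only as a test
#' oracle.
#'
#' Bounds at the big-M sentinel magnitude (>= 1e5) are not enumerated as
#' active states; the returned candidate's primal feasibility is verified,
#' so the oracle is exact whenever the optimum does not touch a sentinel
#' bound.
#'
#' @param model A [wbm()] model with at most 12 reactions.
#' @param settings A [solver_settings()].
#' @return A `flux_solution`.
#' @export
qp_oracle <- function(model, settings = solver_settings()) {
  prob <- prepare_problem(model, settings)
  rx <- prob$rx
  n <- nrow(rx)
  if (n > 12) {
    abort("qp_oracle is limited to models with at most 12 reactions.",
          class = "dietwbm_oracle_error")
  }
  S <- as.matrix(prob$S)
  keep <- independent_rows(S)
  S <- S[keep, , drop = FALSE]

  states <- vector("list", n)
  for (i in seq_len(n)) {
    if (rx$lb[i] == rx$ub[i]) {
      states[[i]] <- "pin"
    } else {
      s <- "free"
      if (abs(rx$lb[i]) < 1e5) s <- c(s, "lb")
      if (abs(rx$ub[i]) < 1e5) s <- c(s, "ub")
      states[[i]] <- s
    }
  }
  grid_size <- prod(lengths(states))
  if (grid_size > 3e5) {
    abort("qp_oracle active-set enumeration too large for this model.",
          class = "dietwbm_oracle_error")
  }
  grid <- expand.grid(states, stringsAsFactors = FALSE)

  best_v <- NULL; best_obj <- Inf
  tol <- 1e-7
  for (g in seq_len(nrow(grid))) {
    st <- as.character(unlist(grid[g, ]))
    fixed_val <- ifelse(st == "pin", rx$lb,
                 ifelse(st == "lb", rx$lb,
                 ifelse(st == "ub", rx$ub, NA_real_)))
    act <- !is.na(fixed_val)
    v <- numeric(n)
    if (all(act)) {
      v <- fixed_val
    } else {
      b <- if (any(act)) -as.numeric(S[, act, drop = FALSE] %*% fixed_val[act])
           else rep(0, nrow(S))
      SF <- S[, !act, drop = FALSE]
      sv <- svd(SF)
      pos <- sv$d > max(sv$d[1], 1) * 1e-10
      # least-norm solution of SF vF = b
      ub_ <- crossprod(sv$u[, pos, drop = FALSE], b)
      vF <- sv$v[, pos, drop = FALSE] %*% (ub_ / sv$d[pos])
      v[act] <- fixed_val[act]; v[!act] <- vF
    }
    if (max(abs(as.numeric(S %*% v))) > tol * max(1, max(abs(v)))) next
    if (any(v < rx$lb - tol) || any(v > rx$ub + tol)) next
    obj <- sum(v^2)
    if (obj < best_obj - 1e-12) { best_obj <- obj; best_v <- v }
  }
  if (is.null(best_v)) {
    return(new_flux_solution(model, NULL, "infeasible", backend = "oracle"))
  }
  new_flux_solution(model, best_v, "optimal", objective = best_obj,
                    backend = "oracle")
}
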