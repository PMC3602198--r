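# LP assembly: a model is translated once into an LP structure
# (S v = 0, lb <= v <= ub); aggregates and fixing rows are appended columns
# and rows on top of it.

lp_struct <- function(model) {
  S <- stoichiometric_matrix(model)
  bb <- reaction_bounds(model)
  list(A = S, b = rep(0, nrow(S)), lb = bb$lb, ub = bb$ub,
       vars = colnames(S))
}

# aggregate flux variable: sum(coefs * v) - v_name = 0
lp_add_aggregate <- function(lp, name, coefs, lb = -1e6, ub = 1e6) {
  n <- ncol(lp$A)
  newcol <- matrix(0, nrow(lp$A), 1)
  A <- cbind(lp$A, newcol)
  row <- numeric(n + 1L)
  row[match(names(coefs), lp$vars)] <- coefs
  row[n + 1L] <- -1
  A <- rbind(A, row)
  lp$A <- unname(A)
  lp$b <- c(lp$b, 0)
  lp$lb <- c(lp$lb, lb)
  lp$ub <- c(lp$ub, ub)
  lp$vars <- c(lp$vars, name)
  lp
}

# inequality sum(coefs * v) >= value (dir 1) or <= value (dir -1),
# via a non-negative surplus/slack column
lp_add_bound_row <- function(lp, coefs, value, dir) {
  n <- ncol(lp$A)
  A <- cbind(lp$A, matrix(0, nrow(lp$A), 1))
  row <- numeric(n + 1L)
  row[match(names(coefs), lp$vars)] <- coefs
  row[n + 1L] <- -dir
  A <- rbind(A, row)
  lp$A <- unname(A)
  lp$b <- c(lp$b, value)
  lp$lb <- c(lp$lb, 0)
  lp$ub <- c(lp$ub, Inf)
  lp$vars <- c(lp$vars, paste0("..slack", ncol(A)))
  lp
}

lp_set_var_bounds <- function(lp, name, lb = NULL, ub = NULL) {
  j <- match(name, lp$vars)
  if (is.na(j)) stop("unknown LP variable: ", name, call. = FALSE)
  if (!is.null(lb)) lp$lb[j] <- lb
  if (!is.null(ub)) lp$ub[j] <- ub
  lp
}

lp_optimize <- function(lp, objective, sense = "max") {
  obj <- numeric(ncol(lp$A))
  if (is.character(objective)) {
    j <- match(objective, lp$vars)
    if (is.na(j)) stop("unknown objective variable: ", objective, call. = FALSE)
    obj[j] <- 1
  } else {
    obj[match(names(objective), lp$vars)] <- objective
  }
  res <- solve_lp(lp$A, lp$b, lp$lb, lp$ub, obj, sense)
  res$vars <- lp$vars
  res
}

#' Flux balance analysis: optimize a reaction flux
#'
#' Solves `sense(c' v)` subject to the pseudo-steady-state constraint
#' `S v = 0` and the flux bounds `lb <= v <= ub`. The solver status is
#' reported faithfully: a feasible model with a zero optimum reports
#' `"optimal"` with objective 0; only true LP infeasibility reports
#' `"infeasible"`.
#'
#' @param model A `cb_model`.
#' @param objective Reaction id; defaults to the model objective (biomass).
#' @param sense `"max"` or `"min"`.
#' @return A `flux_result`: list with `status`, `objective_value` and
#'   `fluxes` (named vector over all reactions, mmol/gDCW/h; biomass 1/h).
#' @export
optimize_fluxes <- function(model, objective = NULL,
                            sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (is.null(objective)) objective <- model$objective
  if (is.null(objective) || !(objective %in% names(model$reactions))) {
    stop("invalid objective reaction id: ",
         if (is.null(objective)) "<null>" else objective, call. = FALSE)
  }
  lp <- lp_struct(model)
  res <- lp_optimize(lp, objective, sense)
  as_flux_result(res, lp, objective)
}

as_flux_result <- function(res, lp, objective) {
  n_rxn <- length(lp$vars[!startsWith(lp$vars, "..")])
  fluxes <- if (res$status == "optimal") {
    stats::setNames(res$x[seq_along(lp$vars)], lp$vars)
  } else {
    stats::setNames(rep(NA_real_, length(lp$vars)), lp$vars)
  }
  fluxes <- fluxes[!startsWith(names(fluxes), "..")]
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal") res$objective
                                   else NA_real_,
                 objective = objective,
                 fluxes = fluxes),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> status: %s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", objective (%s): %.6g",
                paste(x$objective, collapse = "+"), x$objective_value))
  }
  cat("\n")
  invisible(x)
}

#' Lexicographic (ordered multi-objective) FBA
#'
#' Optimizes a sequence of objectives, fixing each stage's optimum (within
#' 1e-6 relative tolerance) as a constraint before the next stage. This
#' resolves alternate optima deterministically: the headline
#' (growth, product, byproduct) triples reported by the scanning functions
#' are always produced this way, never by reading an arbitrary optimal
#' vertex of a single solve.
#'
#' @param model A `cb_model`.
#' @param objectives List of `list(id =, sense =)` stages, in priority
#'   order. `id` is a reaction id or the name of an entry of `aggregates`.
#' @param aggregates Named list of linear flux combinations (named numeric
#'   coefficient vectors over reaction ids), usable as objectives; e.g. the
#'   molar byproduct sum.
#' @return A `flux_result` whose `stage_values` element records each
#'   stage's optimum.
#' @export
lexicographic_optimize <- function(model, objectives, aggregates = list()) {
  stopifnot(length(objectives) >= 1L)
  lp <- lp_struct(model)
  for (nm in names(aggregates)) {
    lp <- lp_add_aggregate(lp, nm, aggregates[[nm]])
  }
  stage_values <- numeric(length(objectives))
  res <- NULL
  for (k in seq_along(objectives)) {
    ob <- objectives[[k]]
    sense <- match.arg(ob$sense, c("max", "min"))
    res <- lp_optimize(lp, ob$id, sense)
    if (res$status != "optimal") {
      fr <- as_flux_result(res, lp, ob$id)
      fr$stage_values <- rep(NA_real_, length(objectives))
      return(fr)
    }
    stage_values[k] <- res$objective
    if (k < length(objectives)) {
      eps <- 1e-6 * max(1, abs(res$objective))
      coefs <- stats::setNames(1, ob$id)
      if (sense == "max") {
        lp <- lp_add_bound_row(lp, coefs, res$objective - eps, dir = 1)
      } else {
        lp <- lp_add_bound_row(lp, coefs, res$objective + eps, dir = -1)
      }
    }
  }
  fr <- as_flux_result(res, lp, objectives[[length(objectives)]]$id)
  fr$objective_value <- stage_values[length(stage_values)]
  fr$stage_values <- stage_values
  names(fr$stage_values) <- vapply(objectives, `[[`, character(1L), "id")
  fr
}

#' Flux variability analysis
#'
#' For each listed reaction, minimizes and maximizes its flux subject to
#' the growth objective attaining at least `fraction_of_optimum` of its
#' optimum.
#'
#' @param model A `cb_model` with an objective.
#' @param reaction_ids Reactions to scan; default all.
#' @param fraction_of_optimum Fraction in \[0, 1\].
#' @return `data.frame` with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, reaction_ids = NULL,
                             fraction_of_optimum = 1) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  if (is.null(reaction_ids)) reaction_ids <- names(model$reactions)
  wt <- optimize_fluxes(model)
  if (wt$status != "optimal") stop("model infeasible", call. = FALSE)
  lp <- lp_struct(model)
  floor_val <- fraction_of_optimum * wt$objective_value
  # relax by the lexicographic tolerance so fraction = 1 stays feasible
  lp <- lp_add_bound_row(lp, stats::setNames(1, model$objective),
                         floor_val - 1e-6 * max(1, abs(floor_val)), dir = 1)
  out <- data.frame(reaction = reaction_ids,
                    min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reaction_ids)) {
    lo <- lp_optimize(lp, reaction_ids[i], "min")
    hi <- lp_optimize(lp, reaction_ids[i], "max")
    if (lo$status == "optimal") out$min[i] <- lo$objective
    if (hi$status == "optimal") out$max[i] <- hi$objective
  }
  out
}

#' Reactions essential for growth
#'
#' A reaction is essential iff forcing its bounds to (0, 0) drops the
#' optimal growth below `threshold_fraction` of the wild-type optimum.
#'
#' @param model A `cb_model` with positive wild-type growth.
#' @param threshold_fraction Fraction of the wild-type optimum (default 1%).
#' @return Character vector of essential reaction ids.
#' @export
essential_reactions <- function(model, threshold_fraction = 0.01) {
  wt <- optimize_fluxes(model)
  if (wt$status != "optimal" || wt$objective_value <= 0) {
    stop("wild-type optimum must be positive", call. = FALSE)
  }
  thr <- threshold_fraction * wt$objective_value
  ess <- character()
  for (rid in names(model$reactions)) {
    m2 <- set_reaction_bounds(model, rid, 0, 0)
    r <- optimize_fluxes(m2)
    if (r$status != "optimal" || r$objective_value < thr) {
      ess <- c(ess, rid)
    }
  }
  ess
}

#' Genes essential for growth
#'
#' Single-gene deletions with GPR semantics: reactions whose rule evaluates
#' inactive under the deletion get bounds (0, 0); a gene is essential iff
#' the resulting optimal growth falls below `threshold_fraction` of the
#' wild-type optimum.
#'
#' @inheritParams essential_reactions
#' @return Character vector of essential gene ids.
#' @export
essential_genes <- function(model, threshold_fraction = 0.01) {
  wt <- optimize_fluxes(model)
  if (wt$status != "optimal" || wt$objective_value <= 0) {
    stop("wild-type optimum must be positive", call. = FALSE)
  }
  thr <- threshold_fraction * wt$objective_value
  ess <- character()
  for (g in model$genes) {
    m2 <- apply_gene_knockout(model, g)$model
    r <- optimize_fluxes(m2)
    if (r$status != "optimal" || r$objective_value < thr) {
      ess <- c(ess, g)
    }
  }
  ess
}

#' Flux-response curve over a scanned exchange flux
#'
#' At each scanned value the exchange flux is fixed as an equality
#' (`lb = ub = -value` for an uptake; pass `uptake = FALSE` to scan a
#' secretion) and the objective reaction is both maximized and minimized.
#' This is the oxygen-response analysis: scanning the oxygen uptake rate
#' from 0 to 30 mmol/gDCW/h at fixed glucose uptake with the 2,3-BD
#' secretion rate as objective. Fixing (rather than capping) the uptake is
#' what produces the declining branch at high oxygen: the cell is forced
#' to over-respire.
#'
#' @param model A `cb_model`.
#' @param scanned_exchange Exchange reaction id.
#' @param values Non-negative uptake rates (mmol/gDCW/h) to fix.
#' @param objective Objective reaction id.
#' @param uptake Scan as uptake (`lb = ub = -value`, default) or secretion.
#' @return A `flux_response_curve` data.frame: `value`, `max_objective`,
#'   `min_objective`, `feasible`. Infeasible points carry `NA` and are
#'   never interpolated.
#' @export
flux_response <- function(model, scanned_exchange, values, objective,
                          uptake = TRUE) {
  stopifnot(all(is.finite(values)))
  if (!scanned_exchange %in% names(model$reactions)) {
    stop("unknown exchange reaction: ", scanned_exchange, call. = FALSE)
  }
  out <- data.frame(value = values, max_objective = NA_real_,
                    min_objective = NA_real_, feasible = FALSE)
  for (i in seq_along(values)) {
    v <- if (uptake) -values[i] else values[i]
    m2 <- set_reaction_bounds(model, scanned_exchange, v, v)
    hi <- optimize_fluxes(m2, objective, "max")
    lo <- optimize_fluxes(m2, objective, "min")
    if (hi$status == "optimal" && lo$status == "optimal") {
      out$max_objective[i] <- hi$objective_value
      out$min_objective[i] <- lo$objective_value
      out$feasible[i] <- TRUE
    }
  }
  class(out) <- c("flux_response_curve", class(out))
  out
}

#' Molar byproduct aggregate coefficients
#'
#' Unweighted molar sum of the listed secretion fluxes (the definition of
#' the byproduct formation rate: ethanol plus the lactic, acetic, succinic
#' and formic organic acids). With `mass_weighted = TRUE` each flux is
#' weighted by its molar mass in g/mmol instead.
#'
#' @param byproduct_exchanges Character vector of exchange reaction ids.
#' @param mass_weighted Logical.
#' @param molar_masses Named g/mol vector, needed when `mass_weighted`.
#' @return Named numeric coefficient vector.
#' @export
byproduct_aggregate <- function(byproduct_exchanges, mass_weighted = FALSE,
                                molar_masses = NULL) {
  if (length(byproduct_exchanges) == 0L) {
    stop("empty byproduct set", call. = FALSE)
  }
  if (!mass_weighted) {
    return(stats::setNames(rep(1, length(byproduct_exchanges)),
                           byproduct_exchanges))
  }
  mm <- molar_masses[byproduct_exchanges]
  if (any(is.na(mm))) stop("missing molar masses", call. = FALSE)
  stats::setNames(mm / 1000, byproduct_exchanges)
}

#' Scan the product/byproduct flux solution space
#'
#' Computes the maximal growth rate over a grid of fixed (product
#' secretion, aggregate byproduct secretion) rates: the flux solution
#' space whose 3-D surface/contour representation is used to read off how
#' the optimal-growth state trades off product against byproducts. The
#' grid spans \[0, max feasible\] on each axis (maxima found by LP first);
#' infeasible cells are `NA`. The unconstrained optimum point is computed
#' by lexicographic optimization: maximal growth, then maximal product,
#' then minimal byproducts.
#'
#' @param model A `cb_model` with a biomass objective.
#' @param product_exchange Product secretion exchange id (e.g. 2,3-BD).
#' @param byproduct_exchanges Exchange ids aggregated (molar sum) as the
#'   byproduct axis.
#' @param grid `c(n1, n2)` resolution (default 21 x 21, linear spacing).
#' @param mass_weighted,molar_masses Passed to [byproduct_aggregate()].
#' @return A `phase_surface`: list with `axis1` (product rates), `axis2`
#'   (byproduct rates), `growth` (n1 x n2 matrix, NA = infeasible) and
#'   `optimum_point` (named vector: growth, product_rate, byproduct_rate).
#' @export
solution_space_scan <- function(model, product_exchange,
                                byproduct_exchanges, grid = c(21L, 21L),
                                mass_weighted = FALSE, molar_masses = NULL) {
  agg <- byproduct_aggregate(byproduct_exchanges, mass_weighted, molar_masses)
  if (!product_exchange %in% names(model$reactions)) {
    stop("unknown product exchange: ", product_exchange, call. = FALSE)
  }
  missing <- setdiff(byproduct_exchanges, names(model$reactions))
  if (length(missing) > 0L) {
    stop("unknown byproduct exchanges: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  base <- lp_struct(model)
  base <- lp_add_aggregate(base, "..byp", agg)

  pmax_res <- lp_optimize(base, product_exchange, "max")
  bmax_res <- lp_optimize(base, "..byp", "max")
  if (pmax_res$status != "optimal" || bmax_res$status != "optimal") {
    stop("model infeasible: cannot size the scan grid", call. = FALSE)
  }
  axis1 <- seq(0, max(0, pmax_res$objective), length.out = grid[1L])
  axis2 <- seq(0, max(0, bmax_res$objective), length.out = grid[2L])
  growth <- matrix(NA_real_, grid[1L], grid[2L])
  for (i in seq_along(axis1)) {
    lp1 <- lp_set_var_bounds(base, product_exchange,
                             lb = axis1[i], ub = axis1[i])
    for (j in seq_along(axis2)) {
      lp2 <- lp_set_var_bounds(lp1, "..byp", lb = axis2[j], ub = axis2[j])
      r <- lp_optimize(lp2, model$objective, "max")
      if (r$status == "optimal") growth[i, j] <- r$objective
    }
  }
  opt <- lexicographic_optimize(model, list(
    list(id = model$objective, sense = "max"),
    list(id = product_exchange, sense = "max"),
    list(id = "byproducts", sense = "min")),
    aggregates = list(byproducts = agg))
  optimum_point <- c(growth = unname(opt$stage_values[1L]),
                     product_rate = unname(opt$stage_values[2L]),
                     byproduct_rate = unname(opt$stage_values[3L]))
  structure(list(axis1 = axis1, axis2 = axis2, growth = growth,
                 optimum_point = optimum_point,
                 product_exchange = product_exchange,
                 byproduct_exchanges = byproduct_exchanges),
            class = "phase_surface")
}

#' @export
print.phase_surface <- function(x, ...) {
  cat(sprintf("<phase_surface> %d x %d grid over %s vs %d byproducts\n",
              length(x$axis1), length(x$axis2), x$product_exchange,
              length(x$byproduct_exchanges)))
  cat(sprintf("  feasible cells: %d / %d\n", sum(!is.na(x$growth)),
              length(x$growth)))
  op <- x$optimum_point
  cat(sprintf("  optimum point: growth %.4f 1/h, product %.3f, byproducts %.3f mmol/gDCW/h\n",
              op[["growth"]], op[["product_rate"]], op[["byproduct_rate"]]))
  invisible(x)
}

#' Long-format table of a phase surface
#' @param surface A `phase_surface`.
#' @return `data.frame` with `product_rate`, `byproduct_rate`, `growth`.
#' @export
surface_to_table <- function(surface) {
  data.frame(
    product_rate = rep(surface$axis1, times = length(surface$axis2)),
    byproduct_rate = rep(surface$axis2, each = length(surface$axis1)),
    growth = as.vector(surface$growth))
}

#' Verify a flux result against the model constraints
#'
#' Asserts the pseudo-steady-state residual `max |S v|` and the bound
#' violations of an optimal flux result; used throughout the test suite.
#'
#' @param model The model the result came from.
#' @param result A `flux_result`.
#' @param tol Tolerance (default 1e-6).
#' @return Invisibly `TRUE`; stops otherwise.
#' @export
check_flux_result <- function(model, result, tol = 1e-6) {
  stopifnot(result$status == "optimal")
  S <- stoichiometric_matrix(model)
  v <- result$fluxes[colnames(S)]
  resid <- max(abs(S %*% v))
  if (resid > tol) stop("steady-state residual ", resid, call. = FALSE)
  bb <- reaction_bounds(model)
  if (any(v < bb$lb - tol) || any(v > bb$ub + tol)) {
    stop("flux bound violation", call. = FALSE)
  }
  invisible(TRUE)
}
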