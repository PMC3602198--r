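#' Construct a constraint-based metabolic model
#'
#' A `cb_model` bundles metabolites, reactions (with stoichiometry, flux
#' bounds and GPR rules), a gene list and an objective reaction. The implied
#' stoichiometric matrix `S` (one row per metabolite, one column per
#' reaction) carries the pseudo-steady-state constraint `S v = 0` used by all
#' flux analyses. Fluxes are in mmol/gDCW/h; the biomass (objective) reaction
#' flux is the specific growth rate in 1/h.
#'
#' @param id Model identifier.
#' @param metabolites `data.frame` with columns `id`, `name`, `formula`,
#'   `charge`, `compartment`. `formula` may be `NA`; `compartment` must be
#'   non-empty (`"c"` cytosol, `"e"` extracellular).
#' @param reactions List of reactions, each a list with elements `id`,
#'   `name`, `stoichiometry` (named numeric, negative = consumed),
#'   `lower_bound`, `upper_bound`, `gpr` (rule text, `""` for spontaneous),
#'   `subsystem`, `ec_numbers` (character vector), and optionally
#'   `is_exchange`. Exchange status is auto-detected for single-metabolite
#'   reactions touching the extracellular compartment.
#' @param genes Character vector of gene ids. Genes referenced by GPR rules
#'   but missing here are tolerated with a warning (the rule leaf is treated
#'   as present), so partial models load.
#' @param objective Reaction id of the objective (biomass by convention).
#' @param annotations Free-form named list.
#' @param validate Run [validate_model()] (default `TRUE`).
#' @return An object of class `cb_model`.
#' @seealso [read_model()], [write_model()], [optimize_fluxes()]
#' @export
new_model <- function(id, metabolites, reactions, genes = character(),
                      objective = NULL, annotations = list(),
                      validate = TRUE) {
  stopifnot(is.data.frame(metabolites), is.list(reactions))
  need <- c("id", "name", "formula", "charge", "compartment")
  for (col in setdiff(need, names(metabolites))) {
    metabolites[[col]] <- if (col == "charge") NA_integer_ else NA_character_
  }
  metabolites <- metabolites[, need]
  metabolites$id <- as.character(metabolites$id)
  metabolites$compartment <- as.character(metabolites$compartment)

  rxns <- lapply(reactions, normalize_reaction, metabolites = metabolites)
  rxn_ids <- vapply(rxns, `[[`, character(1L), "id")
  names(rxns) <- rxn_ids

  model <- structure(list(
    id = as.character(id),
    metabolites = metabolites,
    reactions = rxns,
    genes = as.character(genes),
    objective = objective,
    annotations = annotations
  ), class = "cb_model")

  # GPR leaves absent from the gene list: warn, treat as present
  gpr_all <- unique(unlist(lapply(model$reactions,
                                  function(r) gpr_genes(r$gpr_tree))))
  missing_genes <- setdiff(gpr_all, model$genes)
  if (length(missing_genes) > 0L) {
    warning("GPR genes absent from model gene list (treated as present): ",
            paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  if (validate) validate_model(model)
  model
}

normalize_reaction <- function(r, metabolites) {
  stopifnot(!is.null(r$id))
  st <- r$stoichiometry
  st <- st[st != 0]
  defaults <- list(name = r$id, lower_bound = -1000, upper_bound = 1000,
                   gpr = "", subsystem = "", ec_numbers = character())
  for (f in names(defaults)) if (is.null(r[[f]])) r[[f]] <- defaults[[f]]
  mets <- names(st)
  comp <- metabolites$compartment[match(mets, metabolites$id)]
  auto_ex <- length(st) == 1L && !is.na(comp[1L]) && comp[1L] == "e"
  is_ex <- if (is.null(r$is_exchange)) auto_ex else isTRUE(r$is_exchange)
  list(id = as.character(r$id), name = as.character(r$name),
       stoichiometry = st,
       lower_bound = as.numeric(r$lower_bound),
       upper_bound = as.numeric(r$upper_bound),
       gpr = as.character(r$gpr),
       gpr_tree = parse_gpr(r$gpr),
       subsystem = as.character(r$subsystem),
       ec_numbers = as.character(r$ec_numbers),
       is_exchange = is_ex)
}

#' Validate a constraint-based model
#'
#' Checks id uniqueness, that every stoichiometry key resolves to a declared
#' metabolite, `lower_bound <= upper_bound`, finite non-zero coefficients,
#' non-empty compartments and that the objective resolves. All offenses are
#' collected and reported together.
#'
#' @param model A `cb_model`.
#' @return Invisibly `TRUE`; stops with the full offense list otherwise.
#' @export
validate_model <- function(model) {
  errs <- character()
  mids <- model$metabolites$id
  if (anyDuplicated(mids)) {
    errs <- c(errs, paste("duplicate metabolite ids:",
                          paste(unique(mids[duplicated(mids)]), collapse = ", ")))
  }
  rids <- vapply(model$reactions, `[[`, character(1L), "id")
  if (anyDuplicated(rids)) {
    errs <- c(errs, paste("duplicate reaction ids:",
                          paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  }
  bad_comp <- is.na(model$metabolites$compartment) |
    !nzchar(model$metabolites$compartment)
  if (any(bad_comp)) {
    errs <- c(errs, paste("metabolites with empty compartment:",
                          paste(mids[bad_comp], collapse = ", ")))
  }
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoichiometry), mids)
    if (length(unknown) > 0L) {
      errs <- c(errs, sprintf("reaction %s references undeclared metabolites: %s",
                              r$id, paste(unknown, collapse = ", ")))
    }
    if (!all(is.finite(r$stoichiometry))) {
      errs <- c(errs, sprintf("reaction %s has non-finite coefficients", r$id))
    }
    if (length(r$stoichiometry) == 0L && !r$is_exchange) {
      errs <- c(errs, sprintf("reaction %s has empty stoichiometry", r$id))
    }
    if (r$lower_bound > r$upper_bound) {
      errs <- c(errs, sprintf("reaction %s has lower_bound > upper_bound (%g > %g)",
                              r$id, r$lower_bound, r$upper_bound))
    }
  }
  if (!is.null(model$objective) && !(model$objective %in% rids)) {
    errs <- c(errs, sprintf("objective reaction '%s' not in model", model$objective))
  }
  if (length(errs) > 0L) {
    stop("model validation failed:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `cb_model`.
#' @return Dense numeric matrix `S`, metabolites in rows, reactions in
#'   columns, dimnames set to the respective ids.
#' @export
stoichiometric_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

reaction_ids <- function(model) names(model$reactions)

reaction_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, numeric(1L), "lower_bound"),
       ub = vapply(model$reactions, `[[`, numeric(1L), "upper_bound"))
}

#' Change the bounds of one reaction
#' @param model A `cb_model`.
#' @param reaction_id Reaction id.
#' @param lb,ub New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model (input untouched).
#' @export
set_reaction_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  if (!reaction_id %in% names(model$reactions)) {
    stop("unknown reaction: ", reaction_id, call. = FALSE)
  }
  r <- model$reactions[[reaction_id]]
  if (!is.null(lb)) r$lower_bound <- lb
  if (!is.null(ub)) r$upper_bound <- ub
  if (r$lower_bound > r$upper_bound) {
    stop(sprintf("lower_bound > upper_bound for %s (%g > %g)",
                 reaction_id, r$lower_bound, r$upper_bound), call. = FALSE)
  }
  model$reactions[[reaction_id]] <- r
  model
}

#' Find the exchange reaction of a metabolite
#'
#' @param model A `cb_model`.
#' @param metabolite_id Metabolite id (typically extracellular, e.g.
#'   `"glc__D_e"`).
#' @return The reaction id.
#' @export
exchange_reaction_for <- function(model, metabolite_id) {
  if (!metabolite_id %in% model$metabolites$id) {
    stop("unknown metabolite: ", metabolite_id, call. = FALSE)
  }
  hits <- vapply(model$reactions, function(r) {
    r$is_exchange && metabolite_id %in% names(r$stoichiometry)
  }, logical(1L))
  if (!any(hits)) {
    stop("no exchange reaction for metabolite ", metabolite_id, call. = FALSE)
  }
  names(model$reactions)[which(hits)[1L]]
}

#' Constrain the exchange flux of a metabolite
#'
#' Sets the bounds of the metabolite's exchange reaction. Sign convention:
#' negative flux = uptake, positive = secretion, so e.g. `lb = -10, ub = 0`
#' caps uptake at 10 mmol/gDCW/h and forbids secretion, and `lb = 0, ub = 0`
#' forces a zero-secretion constraint for species not produced during
#' fermentation.
#'
#' @param model A `cb_model`.
#' @param metabolite_id Metabolite id with an exchange reaction.
#' @param lb,ub New bounds (mmol/gDCW/h), `lb <= ub`.
#' @return The modified model.
#' @export
set_exchange_bounds <- function(model, metabolite_id, lb, ub) {
  if (lb > ub) {
    stop(sprintf("lb > ub (%g > %g) for exchange of %s", lb, ub, metabolite_id),
         call. = FALSE)
  }
  rid <- exchange_reaction_for(model, metabolite_id)
  set_reaction_bounds(model, rid, lb = lb, ub = ub)
}

#' Summary statistics of a model
#'
#' Transport reactions are those spanning the two compartments or flagged as
#' exchanges; the rest are biochemical. ORF coverage is
#' `100 * assigned_genes / total_orfs`, reported rounded half-up to two
#' decimals (like the value 19.57% for 1,074 genes of 5,488 ORFs).
#'
#' @param model A `cb_model`.
#' @param total_orfs Total open reading frames of the genome (> 0).
#' @param assigned_genes Number of ORFs assigned in the network; defaults to
#'   the model's gene count.
#' @return A list of class `model_stats` with `n_reactions`,
#'   `n_biochemical`, `n_transport`, `n_metabolites`, `n_genes` and
#'   `orf_coverage_percent`.
#' @export
model_stats <- function(model, total_orfs, assigned_genes = NULL) {
  if (total_orfs <= 0) stop("total_orfs must be > 0", call. = FALSE)
  if (is.null(assigned_genes)) assigned_genes <- length(model$genes)
  comp <- model$metabolites$compartment
  names(comp) <- model$metabolites$id
  is_transport <- vapply(model$reactions, function(r) {
    r$is_exchange || length(unique(comp[names(r$stoichiometry)])) > 1L
  }, logical(1L))
  structure(list(
    n_reactions = length(model$reactions),
    n_biochemical = sum(!is_transport),
    n_transport = sum(is_transport),
    n_metabolites = nrow(model$metabolites),
    n_genes = length(model$genes),
    orf_coverage_percent = round_half_up(100 * assigned_genes / total_orfs, 2L)
  ), class = "model_stats")
}

#' @export
print.model_stats <- function(x, ...) {
  cat("Model statistics\n")
  cat(sprintf("  reactions:    %d (%d biochemical + %d transport)\n",
              x$n_reactions, x$n_biochemical, x$n_transport))
  cat(sprintf("  metabolites:  %d\n", x$n_metabolites))
  cat(sprintf("  genes:        %d\n", x$n_genes))
  cat(sprintf("  ORF coverage: %.2f%%\n", x$orf_coverage_percent))
  invisible(x)
}

round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Parse an elemental formula
#'
#' @param formula Formula text such as `"C21H27N7O14P2"`.
#' @return Named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) {
    stop("empty formula", call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1L]]
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1L]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("unparseable formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", parts)
  ct <- sub("^[A-Za-z]+", "", parts)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  tapply(ct, el, sum)[unique(el)]
}

#' Check the elemental (and charge) balance of a reaction
#'
#' Sums `coefficient * element count` over all participating metabolites.
#' Exchange reactions are boundary sinks/sources and are skipped; reactions
#' with any participant lacking a formula are reported unverifiable. Charge
#' is checked as the pseudo-element `"charge"` when every participant
#' carries one.
#'
#' @param model A `cb_model`.
#' @param reaction_id Reaction id to check.
#' @return A list with `status` (`"balanced"`, `"imbalanced"`, `"skipped"`
#'   for exchanges, `"unverifiable"`) and `imbalance` (named numeric of
#'   non-zero element sums; empty when balanced).
#' @param tol Absolute tolerance on element sums.
#' @export
check_mass_balance <- function(model, reaction_id, tol = 1e-9) {
  if (!reaction_id %in% names(model$reactions)) {
    stop("unknown reaction: ", reaction_id, call. = FALSE)
  }
  r <- model$reactions[[reaction_id]]
  if (r$is_exchange) {
    return(list(status = "skipped", imbalance = numeric()))
  }
  met <- model$metabolites
  rows <- match(names(r$stoichiometry), met$id)
  formulas <- met$formula[rows]
  if (any(is.na(formulas) | !nzchar(formulas))) {
    return(list(status = "unverifiable", imbalance = numeric()))
  }
  total <- numeric()
  for (k in seq_along(rows)) {
    counts <- parse_formula(formulas[k]) * r$stoichiometry[k]
    for (e in names(counts)) {
      total[e] <- (if (e %in% names(total)) total[e] else 0) + counts[[e]]
    }
  }
  charges <- met$charge[rows]
  if (!any(is.na(charges))) {
    total["charge"] <- sum(charges * r$stoichiometry)
  }
  imb <- total[abs(total) > tol]
  list(status = if (length(imb) == 0L) "balanced" else "imbalanced",
       imbalance = imb)
}

#' @export
print.cb_model <- function(x, ...) {
  cat(sprintf("<cb_model> %s: %d metabolites, %d reactions, %d genes\n",
              x$id, nrow(x$metabolites), length(x$reactions),
              length(x$genes)))
  if (!is.null(x$objective)) cat("  objective:", x$objective, "\n")
  invisible(x)
}
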