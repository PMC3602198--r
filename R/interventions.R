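#' Apply a gene knockout to a model
#'
#' Deletes the given genes: every reaction whose GPR rule evaluates
#' inactive under the deletion (complex member lost and no isozyme left)
#' has its bounds forced to (0, 0). All other reactions are untouched and
#' the input model is not mutated. Idempotent and order-independent over
#' gene sets.
#'
#' @param model A `cb_model`.
#' @param genes Character vector of gene ids; unknown ids are an error.
#' @return List with `model` (the knockout model) and `disabled`
#'   (character vector of disabled reaction ids).
#' @export
apply_gene_knockout <- function(model, genes) {
  unknown <- setdiff(genes, model$genes)
  if (length(unknown) > 0L) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  disabled <- character()
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    if (!gpr_active(r$gpr_tree, genes)) {
      model <- set_reaction_bounds(model, rid, 0, 0)
      disabled <- c(disabled, rid)
    }
  }
  list(model = model, disabled = disabled)
}

#' Lexicographic optimum state (growth, product, byproducts)
#'
#' The deterministic headline triple at the growth optimum: maximal
#' growth, then maximal product secretion at that growth, then minimal
#' molar byproduct secretion at both.
#'
#' @param model A `cb_model` with a biomass objective.
#' @param product_exchange Product exchange reaction id.
#' @param byproduct_exchanges Byproduct exchange ids (molar sum).
#' @return Named vector `growth`, `product_rate`, `byproduct_rate`, or
#'   all-`NA` when infeasible.
#' @export
optimal_state <- function(model, product_exchange, byproduct_exchanges) {
  agg <- byproduct_aggregate(byproduct_exchanges)
  r <- lexicographic_optimize(model, list(
    list(id = model$objective, sense = "max"),
    list(id = product_exchange, sense = "max"),
    list(id = "byproducts", sense = "min")),
    aggregates = list(byproducts = agg))
  if (r$status != "optimal") {
    return(c(growth = NA_real_, product_rate = NA_real_,
             byproduct_rate = NA_real_))
  }
  c(growth = unname(r$stage_values[1L]),
    product_rate = unname(r$stage_values[2L]),
    byproduct_rate = unname(r$stage_values[3L]))
}

#' Single-gene knockout scan
#'
#' Evaluates the wild type and every single-gene deletion mutant by
#' lexicographic FBA (growth max, product max, byproducts min). The wild
#' type is always included as the first row (`gene = "WT"`) for
#' comparison. Mutants whose deletion disables no reaction are reported
#' with the wild-type state (their LP is identical).
#'
#' @param model A `cb_model`.
#' @param product_exchange Product exchange id (e.g. `"EX_btd_e"`).
#' @param byproduct_exchanges Byproduct exchange ids.
#' @param genes Genes to scan; default all model genes.
#' @return `data.frame` of class `knockout_scan`: `gene`, `n_disabled`,
#'   `disabled` (comma-joined reaction ids), `growth`, `product_rate`,
#'   `byproduct_rate`, `feasible`.
#' @export
knockout_scan <- function(model, product_exchange, byproduct_exchanges,
                          genes = NULL) {
  if (is.null(genes)) genes <- model$genes
  wt <- optimal_state(model, product_exchange, byproduct_exchanges)
  if (any(is.na(wt)) || wt[["growth"]] <= 0) {
    stop("wild-type model must be feasible with positive growth",
         call. = FALSE)
  }
  rows <- vector("list", length(genes) + 1L)
  rows[[1L]] <- data.frame(gene = "WT", n_disabled = 0L, disabled = "",
                           growth = wt[["growth"]],
                           product_rate = wt[["product_rate"]],
                           byproduct_rate = wt[["byproduct_rate"]],
                           feasible = TRUE, stringsAsFactors = FALSE)
  for (k in seq_along(genes)) {
    ko <- apply_gene_knockout(model, genes[k])
    if (length(ko$disabled) == 0L) {
      st <- wt
    } else {
      st <- optimal_state(ko$model, product_exchange, byproduct_exchanges)
    }
    rows[[k + 1L]] <- data.frame(
      gene = genes[k], n_disabled = length(ko$disabled),
      disabled = paste(ko$disabled, collapse = ","),
      growth = if (is.na(st[["growth"]])) 0 else st[["growth"]],
      product_rate = st[["product_rate"]],
      byproduct_rate = st[["byproduct_rate"]],
      feasible = !any(is.na(st)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("knockout_scan", class(out))
  out
}

#' Rank knockout candidates
#'
#' Applies the selection criteria for single-gene knockout strategies:
#' maximize the product secretion rate, break ties by minimal byproduct
#' rate, then by gene id. Mutants growing below `min_growth_fraction` of
#' the wild type (and infeasible ones) are excluded so that "high-yield"
#' but non-growing candidates never surface.
#'
#' @param results A [knockout_scan()] table (must contain the `WT` row).
#' @param min_growth_fraction Growth floor relative to wild type.
#' @return The filtered table ordered by rank (wild-type row removed).
#' @export
rank_knockouts <- function(results, min_growth_fraction = 0.5) {
  stopifnot(nrow(results) > 0L, "WT" %in% results$gene)
  wt_growth <- results$growth[results$gene == "WT"][1L]
  cand <- results[results$gene != "WT" & results$feasible &
                    results$growth >= min_growth_fraction * wt_growth, ,
                  drop = FALSE]
  ord <- order(-cand$product_rate, cand$byproduct_rate, cand$gene)
  out <- cand[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reactions able to consume a metabolite
#'
#' A reaction is a consumer iff it can carry flux in a direction that
#' consumes the metabolite under the current bounds: negative coefficient
#' with `upper_bound > 0`, or positive coefficient with
#' `lower_bound < 0` (reversible producer running backwards). Exchange
#' reactions count as consumers of their extracellular species only
#' (secretion removes it from the system).
#'
#' @param model A `cb_model`.
#' @param metabolite_id Metabolite id.
#' @return Character vector of reaction ids.
#' @export
consumers_of <- function(model, metabolite_id) {
  if (!metabolite_id %in% model$metabolites$id) {
    stop("unknown metabolite: ", metabolite_id, call. = FALSE)
  }
  hits <- vapply(model$reactions, function(r) {
    co <- r$stoichiometry[metabolite_id]
    if (is.na(co)) return(FALSE)
    (co < 0 && r$upper_bound > 0) || (co > 0 && r$lower_bound < 0)
  }, logical(1L))
  names(model$reactions)[hits]
}

#' Augment a precursor pool by consumer elimination
#'
#' The in-silico precursor-pool augmentation procedure: all reactions that
#' consume the target precursor are eliminated except those in the product
#' biosynthetic pathway (`protected_pathway`) and reactions essential for
#' growth (evaluated on the unmodified model under the same medium).
#' Elimination blocks only the consuming direction of each reaction
#' (reversible reactions may still produce the precursor). The outcome
#' records the optimum-state triple before and after, and the
#' solution-space surface of the augmented model.
#'
#' @param model A `cb_model`.
#' @param precursor_id Metabolite id of the precursor (e.g. `"pyr_c"`).
#' @param protected_pathway Reaction ids never removed; defaults to the
#'   2,3-BD pathway of the core fixture (acetolactate synthase and
#'   decarboxylase, acetoin reductase, spontaneous diacetyl route,
#'   diacetyl reductase).
#' @param product_exchange,byproduct_exchanges As in [knockout_scan()].
#' @param essentiality_threshold Passed to [essential_reactions()].
#' @param grid Resolution of the after-surface; `NULL` skips the surface.
#' @return An `augmentation_outcome`: list with `precursor`, `removed`,
#'   `protected`, `model` (augmented), `before`/`after` optimum triples,
#'   `feasible`, and `surface` (a [solution_space_scan()] result or
#'   `NULL`).
#' @export
augment_precursor_pool <- function(model, precursor_id,
                                   protected_pathway = c("ACLS", "ACLDC",
                                                         "BTDD_RR",
                                                         "ACLS_SPONT",
                                                         "DAR"),
                                   product_exchange = "EX_btd_e",
                                   byproduct_exchanges = kox_byproduct_exchanges(),
                                   essentiality_threshold = 0.01,
                                   grid = c(21L, 21L)) {
  consumers <- consumers_of(model, precursor_id)
  essential <- essential_reactions(model, essentiality_threshold)
  removed <- setdiff(consumers, union(protected_pathway, essential))
  m2 <- model
  for (rid in removed) {
    co <- m2$reactions[[rid]]$stoichiometry[precursor_id]
    if (co < 0) {
      m2 <- set_reaction_bounds(m2, rid, ub = min(0, m2$reactions[[rid]]$upper_bound))
    } else {
      m2 <- set_reaction_bounds(m2, rid, lb = max(0, m2$reactions[[rid]]$lower_bound))
    }
  }
  before <- optimal_state(model, product_exchange, byproduct_exchanges)
  after <- optimal_state(m2, product_exchange, byproduct_exchanges)
  feasible <- !any(is.na(after))
  surface <- if (feasible && !is.null(grid)) {
    solution_space_scan(m2, product_exchange, byproduct_exchanges, grid)
  } else {
    NULL
  }
  structure(list(precursor = precursor_id, removed = removed,
                 protected = intersect(consumers,
                                       union(protected_pathway, essential)),
                 model = m2, before = before, after = after,
                 feasible = feasible, surface = surface),
            class = "augmentation_outcome")
}

#' Byproduct exchange reactions of the core fixture
#'
#' Ethanol and the organic acids lactate, acetate, succinate and formate.
#' @return Character vector of exchange reaction ids.
#' @export
kox_byproduct_exchanges <- function() {
  c("EX_etoh_e", "EX_lac__D_e", "EX_ac_e", "EX_succ_e", "EX_for_e")
}

#' @export
print.augmentation_outcome <- function(x, ...) {
  cat(sprintf("<augmentation_outcome> precursor %s\n", x$precursor))
  cat(sprintf("  removed %d consumer reaction(s): %s\n", length(x$removed),
              paste(x$removed, collapse = ", ")))
  cat(sprintf("  protected: %s\n", paste(x$protected, collapse = ", ")))
  fmt <- function(s) sprintf("growth %.4f, product %.3f, byproducts %.3f",
                             s[["growth"]], s[["product_rate"]],
                             s[["byproduct_rate"]])
  cat("  before:", fmt(x$before), "\n")
  if (x$feasible) cat("  after: ", fmt(x$after), "\n")
  else cat("  after:  infeasible\n")
  invisible(x)
}
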