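# Shared fixtures and independent oracles for the test suite.

# Linear chain: A_e -> A -> B -> B_e with an uptake cap of 10.
chain_model <- function(uptake = 10) {
  mets <- data.frame(
    id = c("A_e", "A_c", "B_c", "B_e"),
    name = c("A ext", "A", "B", "B ext"),
    formula = c("C1", "C1", "C1", "C1"),
    charge = c(0L, 0L, 0L, 0L),
    compartment = c("e", "c", "c", "e"),
    stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "EX_A", name = "A exchange", stoichiometry = c(A_e = -1),
         lower_bound = -uptake, upper_bound = 0),
    list(id = "At", name = "A transport", stoichiometry = c(A_e = -1, A_c = 1),
         lower_bound = -1000, upper_bound = 1000),
    list(id = "R1", name = "A to B", stoichiometry = c(A_c = -1, B_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "g1"),
    list(id = "Bt", name = "B transport", stoichiometry = c(B_c = -1, B_e = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "EX_B", name = "B exchange", stoichiometry = c(B_e = -1),
         lower_bound = 0, upper_bound = 1000))
  new_model("chain", mets, rxns, genes = "g1", objective = "EX_B")
}

# Two equivalent parallel routes A -> B, each unbounded, total limited by
# uptake; used for variability and essentiality checks.
parallel_model <- function(uptake = 10) {
  mets <- data.frame(
    id = c("A_e", "A_c", "B_c", "B_e"),
    name = c("A ext", "A", "B", "B ext"),
    formula = NA_character_, charge = NA_integer_,
    compartment = c("e", "c", "c", "e"),
    stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "EX_A", stoichiometry = c(A_e = -1),
         lower_bound = -uptake, upper_bound = 0),
    list(id = "At", stoichiometry = c(A_e = -1, A_c = 1),
         lower_bound = -1000, upper_bound = 1000),
    list(id = "P1", stoichiometry = c(A_c = -1, B_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "iso1"),
    list(id = "P2", stoichiometry = c(A_c = -1, B_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "iso2"),
    list(id = "Bt", stoichiometry = c(B_c = -1, B_e = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "EX_B", stoichiometry = c(B_e = -1),
         lower_bound = 0, upper_bound = 1000))
  new_model("parallel", mets, rxns, genes = c("iso1", "iso2"),
            objective = "EX_B")
}

# Brute-force LP oracle: enumerates all basis/bound assignments of a small
# bounded LP (n <= 8) and returns the best feasible vertex objective.
# Independent of the simplex implementation.
brute_force_lp <- function(A, b, lb, ub, obj, sense = "max", tol = 1e-8) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  best <- NULL
  feasible_value <- function(x) {
    if (any(x < lb - tol) || any(x > ub + tol)) return(NULL)
    if (max(abs(A %*% x - b)) > tol) return(NULL)
    sum(obj * x)
  }
  # vertices: pick k <= m basic columns, fix the rest at a bound
  idx <- seq_len(n)
  for (k in 0:min(m, n)) {
    basis_sets <- if (k == 0) list(integer()) else
      utils::combn(idx, k, simplify = FALSE)
    for (B in basis_sets) {
      NBi <- setdiff(idx, B)
      grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(NBi)))
      if (length(NBi) == 0L) grid <- data.frame(row.names = 1)
      for (g in seq_len(nrow(grid))) {
        x <- numeric(n)
        if (length(NBi) > 0L) {
          at_ub <- unlist(grid[g, ], use.names = FALSE)
          x[NBi] <- ifelse(at_ub, ub[NBi], lb[NBi])
        }
        if (k > 0) {
          rhs <- b - A[, NBi, drop = FALSE] %*% x[NBi]
          sol <- tryCatch(qr.solve(A[, B, drop = FALSE], rhs),
                          error = function(e) NULL)
          if (is.null(sol)) next
          x[B] <- sol
          if (max(abs(A %*% x - b)) > tol) next
        }
        v <- feasible_value(x)
        if (!is.null(v)) best <- if (is.null(best)) v else
          if (sense == "max") max(best, v) else min(best, v)
      }
    }
  }
  best
}

# Independent GPR oracle: rewrite the rule into an R logical expression and
# evaluate it with gene presence bindings.
eval_gpr_text <- function(text, deleted) {
  if (!nzchar(trimws(text))) return(TRUE)
  expr <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", text,
                                      ignore.case = TRUE),
               ignore.case = TRUE)
  genes <- unique(regmatches(text,
    gregexpr("[A-Za-z0-9_.:-]+", text))[[1]])
  genes <- setdiff(genes, c("and", "or", "AND", "OR"))
  env <- new.env()
  for (g in genes) assign(g, !(g %in% deleted), envir = env)
  isTRUE(eval(parse(text = expr), envir = env))
}

fixture_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- suppressWarnings(build_core_model())
    cache
  }
})
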