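#' dNMP mole fractions from genomic GC content
#'
#' DNA composition follows directly from the GC content by Chargaff pairing:
#' dG and dC each contribute `gc/2`, dA and dT each `(1-gc)/2`. The
#' K. oxytoca biomass equation uses a GC content of 53% for this conversion.
#'
#' @param gc GC content as a fraction in \[0, 1\].
#' @return Named numeric: `dAMP`, `dTMP`, `dGMP`, `dCMP`, summing to 1.
#' @examples
#' dna_fractions_from_gc(0.53)
#' @export
dna_fractions_from_gc <- function(gc) {
  if (!is.numeric(gc) || is.na(gc) || gc < 0 || gc > 1) {
    stop("gc must be a fraction in [0, 1]", call. = FALSE)
  }
  c(dAMP = (1 - gc) / 2, dTMP = (1 - gc) / 2, dGMP = gc / 2, dCMP = gc / 2)
}

#' Convert a macromolecule mass fraction to monomer coefficients
#'
#' Given the mass fraction of a macromolecule class (g per gDCW), the mole
#' fractions of its monomers and their (residue) molecular weights, the
#' biomass coefficient of monomer i is
#' `1000 * fraction * profile_i / sum_j(profile_j * weight_j)` in mmol/gDCW,
#' so that the coefficients jointly account for exactly `fraction` grams.
#'
#' @param mass_fraction Class mass fraction, g/gDCW.
#' @param profile Named numeric mole fractions (sum 1).
#' @param weights Named numeric monomer weights, g/mol, aligned to
#'   `profile` names. For polymerized classes these are residue weights
#'   (monomer minus water).
#' @return Named numeric, mmol monomer per gDCW.
#' @export
mass_to_mmol_coefficients <- function(mass_fraction, profile, weights) {
  stopifnot(length(profile) > 0L, all(names(profile) %in% names(weights)))
  if (abs(sum(profile) - 1) > 1e-6) {
    stop("monomer profile must sum to 1", call. = FALSE)
  }
  w <- weights[names(profile)]
  if (any(w <= 0)) stop("monomer weights must be positive", call. = FALSE)
  denom <- sum(profile * w)
  if (denom == 0) stop("zero average monomer weight", call. = FALSE)
  1000 * mass_fraction * profile / denom
}

#' Biomass composition object
#'
#' Bundles macromolecular mass fractions (summing to 1 g/gDCW), per-class
#' monomer mole-fraction profiles keyed by model metabolite ids, monomer
#' weights, and the two ATP maintenance parameters: `gam` (growth-associated
#' maintenance, mmol ATP per gDCW formed) and `ngam` (non-growth-associated
#' maintenance, mmol ATP/gDCW/h, installed as an always-on hydrolysis flux).
#'
#' @param fractions Named numeric mass fractions (g/gDCW); names are class
#'   labels such as `protein`, `rna`, `dna`, `lipid`, `carbohydrate`,
#'   `other`. Must sum to 1 within 1e-6.
#' @param profiles Named list (same names) of monomer mole-fraction vectors,
#'   each summing to 1 and keyed by metabolite id.
#' @param weights Named numeric monomer weights (g/mol) covering every
#'   monomer in `profiles`.
#' @param polymer_classes Classes whose weights are residue weights and
#'   whose polymerization releases one water per monomer incorporated.
#' @param gam,ngam Maintenance parameters (see above), both >= 0.
#' @return Object of class `biomass_composition`.
#' @seealso [default_biomass_composition()], [assemble_biomass_reaction()]
#' @export
biomass_composition <- function(fractions, profiles, weights,
                                polymer_classes = c("protein", "rna", "dna",
                                                    "carbohydrate"),
                                gam = 45, ngam = 8.4) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)),
            is.list(profiles))
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("macromolecule mass fractions must sum to 1 g/gDCW", call. = FALSE)
  }
  if (any(fractions < 0 | fractions > 1)) {
    stop("mass fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(fractions), names(profiles))) {
    stop("fractions and profiles must cover the same classes", call. = FALSE)
  }
  for (cl in names(profiles)) {
    p <- profiles[[cl]]
    if (abs(sum(p) - 1) > 1e-6) {
      stop("profile for class '", cl, "' must sum to 1", call. = FALSE)
    }
    if (any(p < 0 | p > 1)) {
      stop("profile fractions for '", cl, "' must lie in [0, 1]", call. = FALSE)
    }
    missing_w <- setdiff(names(p), names(weights))
    if (length(missing_w) > 0L) {
      stop("missing monomer weights: ", paste(missing_w, collapse = ", "),
           call. = FALSE)
    }
  }
  if (gam < 0 || ngam < 0) stop("gam and ngam must be >= 0", call. = FALSE)
  structure(list(fractions = fractions, profiles = profiles,
                 weights = weights, polymer_classes = polymer_classes,
                 gam = gam, ngam = ngam),
            class = "biomass_composition")
}

#' Default Gram-negative biomass composition
#'
#' A documented stand-in composition for an enterobacterium: protein 0.55,
#' RNA 0.20, DNA 0.03, lipid 0.09, carbohydrate 0.06 and other (soluble
#' pool) 0.07 g/gDCW. DNA monomer fractions derive from the GC content via
#' [dna_fractions_from_gc()] (default 53%, the value used for the
#' K. oxytoca biomass equation; the genome-wide figure of 56.05% can be
#' passed instead); in the absence of rRNA/tRNA sequence counts the RNA
#' profile mirrors the same GC rule applied to NMPs. Protein is represented
#' by a four-amino-acid profile and lipid by palmitate, matching the
#' monomers resolvable in the bundled core fixture model; maintenance
#' defaults are GAM 45 mmol ATP/gDCW and NGAM 8.4 mmol ATP/gDCW/h, common
#' enterobacterial values. Everything is configurable.
#'
#' @param gc GC content used for the DNA (and RNA) profiles.
#' @param gam,ngam Maintenance parameters.
#' @return A [biomass_composition()].
#' @export
default_biomass_composition <- function(gc = 0.53, gam = 45, ngam = 8.4) {
  dna <- dna_fractions_from_gc(gc)
  fractions <- c(protein = 0.55, rna = 0.20, dna = 0.03, lipid = 0.09,
                 carbohydrate = 0.06, other = 0.07)
  profiles <- list(
    protein = c(ala__L_c = 0.30, glu__L_c = 0.25, asp__L_c = 0.25,
                gln__L_c = 0.20),
    rna = c(amp_c = (1 - gc) / 2, ump_c = (1 - gc) / 2,
            gmp_c = gc / 2, cmp_c = gc / 2),
    dna = c(damp_c = dna[["dAMP"]], dtmp_c = dna[["dTMP"]],
            dgmp_c = dna[["dGMP"]], dcmp_c = dna[["dCMP"]]),
    lipid = c(hdca_c = 1),
    carbohydrate = c(glycogen_c = 1),
    other = c(glu__L_c = 1)
  )
  biomass_composition(fractions, profiles, monomer_weights(),
                      gam = gam, ngam = ngam)
}

#' Monomer weight table bundled with the package
#'
#' Residue weights (monomer minus one water) for amino acids, NMPs, dNMPs
#' and the glucan residue; the free-molecule weight for palmitate. g/mol.
#' @return Named numeric vector.
#' @export
monomer_weights <- function() {
  c(ala__L_c = 71.08, glu__L_c = 129.12, asp__L_c = 115.09,
    gln__L_c = 128.13,
    amp_c = 329.21, gmp_c = 345.21, cmp_c = 305.18, ump_c = 306.17,
    damp_c = 313.21, dgmp_c = 329.21, dcmp_c = 289.18, dtmp_c = 304.19,
    hdca_c = 256.42, glycogen_c = 162.14)
}

#' Read / write a biomass composition as JSON
#' @param path JSON file.
#' @return [biomass_composition()] for the reader.
#' @export
read_biomass_composition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  biomass_composition(unlist(x$fractions),
                      lapply(x$profiles, unlist),
                      unlist(x$weights),
                      polymer_classes = x$polymer_classes,
                      gam = x$gam, ngam = x$ngam)
}

#' @rdname read_biomass_composition
#' @param composition A `biomass_composition`.
#' @export
write_biomass_composition <- function(composition, path) {
  x <- list(fractions = as.list(composition$fractions),
            profiles = lapply(composition$profiles, as.list),
            weights = as.list(composition$weights),
            polymer_classes = composition$polymer_classes,
            gam = composition$gam, ngam = composition$ngam)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Assemble a biomass reaction from a composition
#'
#' Builds the pseudo-reaction draining monomers at their computed
#' coefficients (mmol per gDCW formed) plus the growth-associated ATP
#' hydrolysis (`gam` ATP + water to ADP + Pi + H+), producing one unit of
#' `biomass_c`. Polymer classes release one water per residue incorporated
#' (their weights are residue weights, the model metabolites free
#' monomers). The per-class mass closure
#' `sum_i(coef_i * weight_i)/1000 = fraction` holds by construction.
#'
#' @param composition A [biomass_composition()].
#' @return Reaction spec (list, as accepted by [new_model()]) with id
#'   `"BIOMASS"`; its flux is the specific growth rate in 1/h. The `ngam`
#'   parameter is not part of this reaction: it is installed by
#'   [attach_biomass()] as the lower bound of the `ATPM` hydrolysis
#'   reaction.
#' @export
assemble_biomass_reaction <- function(composition) {
  cmp <- composition
  st <- numeric()
  add <- function(st, met, coef) {
    st[met] <- (if (met %in% names(st)) st[met] else 0) + coef
    st
  }
  water_release <- 0
  for (cl in names(cmp$fractions)) {
    if (cmp$fractions[[cl]] == 0) next
    coefs <- mass_to_mmol_coefficients(cmp$fractions[[cl]],
                                       cmp$profiles[[cl]], cmp$weights)
    for (m in names(coefs)) st <- add(st, m, -coefs[[m]])
    if (cl %in% cmp$polymer_classes) water_release <- water_release + sum(coefs)
  }
  if (cmp$gam > 0) {
    st <- add(st, "atp_c", -cmp$gam)
    st <- add(st, "h2o_c", -cmp$gam)
    st <- add(st, "adp_c", cmp$gam)
    st <- add(st, "pi_c", cmp$gam)
    st <- add(st, "h_c", cmp$gam)
  }
  if (water_release > 0) st <- add(st, "h2o_c", water_release)
  st <- add(st, "biomass_c", 1)
  list(id = "BIOMASS", name = "Biomass formation",
       stoichiometry = st[st != 0], lower_bound = 0, upper_bound = 1000,
       gpr = "", subsystem = "Biomass and maintenance",
       ec_numbers = character())
}

#' Attach a biomass reaction (and maintenance) to a model
#'
#' Adds the `biomass_c` pseudo-metabolite, the `BIOMASS` reaction from
#' [assemble_biomass_reaction()], a `DM_biomass` drain, and the `ATPM`
#' non-growth maintenance hydrolysis with `lower_bound = ngam` (always-on).
#' The objective is set to `BIOMASS`.
#'
#' @param model A `cb_model` containing every monomer metabolite.
#' @param composition A [biomass_composition()].
#' @return The extended model.
#' @export
attach_biomass <- function(model, composition) {
  rx <- assemble_biomass_reaction(composition)
  monomers <- setdiff(names(rx$stoichiometry), "biomass_c")
  missing <- setdiff(monomers, model$metabolites$id)
  if (length(missing) > 0L) {
    stop("model lacks biomass monomers: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mets <- rbind(model$metabolites,
                data.frame(id = "biomass_c", name = "biomass",
                           formula = NA_character_, charge = NA_integer_,
                           compartment = "c", stringsAsFactors = FALSE))
  rxns <- c(lapply(model$reactions, function(r) {
    r[c("id", "name", "stoichiometry", "lower_bound", "upper_bound",
        "gpr", "subsystem", "ec_numbers", "is_exchange")]
  }), list(rx,
    list(id = "DM_biomass", name = "Biomass drain",
         stoichiometry = c(biomass_c = -1), lower_bound = 0,
         upper_bound = 1000, gpr = "", subsystem = "Biomass and maintenance",
         ec_numbers = character(), is_exchange = FALSE),
    list(id = "ATPM", name = "Non-growth-associated maintenance",
         stoichiometry = c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1,
                           h_c = 1),
         lower_bound = composition$ngam, upper_bound = 1000, gpr = "",
         subsystem = "Biomass and maintenance", ec_numbers = character())))
  new_model(id = model$id, metabolites = mets, reactions = rxns,
            genes = model$genes, objective = "BIOMASS",
            annotations = model$annotations)
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat("<biomass_composition>\n")
  cat("  fractions (g/gDCW):",
      paste(sprintf("%s %.3f", names(x$fractions), x$fractions),
            collapse = ", "), "\n")
  cat(sprintf("  GAM %.1f mmol ATP/gDCW, NGAM %.1f mmol ATP/gDCW/h\n",
              x$gam, x$ngam))
  invisible(x)
}
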