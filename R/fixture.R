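#' Build the curated K. oxytoca central-metabolism core model
#'
#' A programmatic, fully mass- and charge-balanced ~85-reaction model of
#' K. oxytoca central carbon metabolism built for desk-scale constraint-based
#' analysis of 2,3-butanediol (2,3-BD) production. It contains:
#' glycolysis with PTS glucose uptake, the oxidative/non-oxidative pentose
#' phosphate shunt (lumped), full TCA cycle with PEP carboxylase anaplerosis
#' and fumarate reductase, mixed-acid fermentation branches (D-lactate via
#' ldhA, acetate via pta/ackA, ethanol via adhE, formate via pflB, succinate
#' via frdAB), the complete 2,3-BD pathway — acetolactate synthase
#' (budB, EC 2.2.1.6), acetolactate decarboxylase (budA, EC 4.1.1.5),
#' acetoin reductase (budC, EC 1.1.1.4), the spontaneous oxygen-dependent
#' acetolactate to diacetyl conversion and diacetyl reductase
#' (EC 1.1.1.303) — both glycerol utilization routes (oxidative glpK/glpD,
#' EC 2.7.1.30 / 1.1.5.3, and reductive gldA/dhaK, EC 1.1.1.6 / 2.7.1.29),
#' a lumped respiratory chain with oxidative phosphorylation (P/O = 2 for
#' NADH, 1 for the flavin-linked steps), transhydrogenase, lumped monomer
#' biosyntheses (four amino acids, NMPs, dNMPs, palmitate, glycogen) and a
#' composition-derived biomass reaction with growth- and non-growth
#' maintenance from [default_biomass_composition()].
#'
#' The default medium is glucose minimal medium with the glucose uptake rate
#' fixed at `glucose_uptake` mmol/gDCW/h (measured-rate convention) and
#' oxygen uptake capped at `o2_uptake`; fermentation byproduct secretions
#' carry measured-flux-style caps (see `secretion_caps`), mirroring how
#' batch-culture exchange-rate measurements are imposed on genome-scale
#' models of this organism.
#'
#' @param aerobic Open the oxygen exchange (default `TRUE`); `FALSE` closes
#'   it (anaerobic).
#' @param glycerol Use glycerol instead of glucose as carbon source.
#' @param gc GC content for the biomass DNA/RNA profiles.
#' @param composition A [biomass_composition()]; default
#'   [default_biomass_composition()] at `gc`.
#' @param glucose_uptake,o2_uptake Substrate rates, mmol/gDCW/h (positive).
#' @param secretion_caps Named vector of maximum secretion rates
#'   (mmol/gDCW/h) for byproduct exchanges.
#' @return A validated `cb_model` with objective `BIOMASS`.
#' @examples
#' \donttest{
#' model <- build_core_model()
#' sol <- optimize_fluxes(model)
#' sol$objective  # specific growth rate, 1/h
#' }
#' @export
build_core_model <- function(aerobic = TRUE, glycerol = FALSE, gc = 0.53,
                             composition = NULL,
                             glucose_uptake = 10, o2_uptake = 5.2,
                             secretion_caps = c(lac__D_e = 20, etoh_e = 2.5,
                                                for_e = 0.5, ac_e = 2,
                                                succ_e = 1, actn__R_e = 1)) {
  if (is.null(composition)) {
    composition <- default_biomass_composition(gc = gc)
  }
  mets <- kox_metabolites()
  rxns <- kox_reactions()
  model <- new_model(id = "kox_core", metabolites = mets, reactions = rxns,
                     genes = kox_genes(), objective = NULL,
                     annotations = list(organism = "Klebsiella oxytoca",
                                        scope = "central metabolism core"))
  model <- attach_biomass(model, composition)

  # medium: minimal salts + carbon source + oxygen
  open_free <- c("nh4_e", "pi_e", "h2o_e", "h_e", "co2_e")
  for (m in open_free) model <- set_exchange_bounds(model, m, -1000, 1000)
  if (glycerol) {
    model <- set_exchange_bounds(model, "glc__D_e", 0, 0)
    model <- set_exchange_bounds(model, "glyc_e", -glucose_uptake, 0)
  } else {
    model <- set_exchange_bounds(model, "glc__D_e", -glucose_uptake, 0)
    model <- set_exchange_bounds(model, "glyc_e", 0, 0)
  }
  model <- set_exchange_bounds(model, "o2_e",
                               if (aerobic) -o2_uptake else 0, 0)
  for (m in names(secretion_caps)) {
    model <- set_exchange_bounds(model, m, 0, unname(secretion_caps[[m]]))
  }
  model <- set_exchange_bounds(model, "btd_e", 0, 1000)
  model
}

kox_metabolites <- function() {
  M <- function(id, name, formula, charge, comp) {
    data.frame(id = id, name = name, formula = formula,
               charge = as.integer(charge), compartment = comp,
               stringsAsFactors = FALSE)
  }
  cyt <- list(
    M("g6p_c", "D-glucose 6-phosphate", "C6H11O9P", -2, "c"),
    M("f6p_c", "D-fructose 6-phosphate", "C6H11O9P", -2, "c"),
    M("fdp_c", "D-fructose 1,6-bisphosphate", "C6H10O12P2", -4, "c"),
    M("dhap_c", "dihydroxyacetone phosphate", "C3H5O6P", -2, "c"),
    M("g3p_c", "glyceraldehyde 3-phosphate", "C3H5O6P", -2, "c"),
    M("3pg_c", "3-phospho-D-glycerate", "C3H4O7P", -3, "c"),
    M("pep_c", "phosphoenolpyruvate", "C3H2O6P", -3, "c"),
    M("pyr_c", "pyruvate", "C3H3O3", -1, "c"),
    M("ru5p__D_c", "D-ribulose 5-phosphate", "C5H9O8P", -2, "c"),
    M("r5p_c", "alpha-D-ribose 5-phosphate", "C5H9O8P", -2, "c"),
    M("accoa_c", "acetyl-CoA", "C23H34N7O17P3S", -4, "c"),
    M("coa_c", "coenzyme A", "C21H32N7O16P3S", -4, "c"),
    M("actp_c", "acetyl phosphate", "C2H3O5P", -2, "c"),
    M("cit_c", "citrate", "C6H5O7", -3, "c"),
    M("icit_c", "isocitrate", "C6H5O7", -3, "c"),
    M("akg_c", "2-oxoglutarate", "C5H4O5", -2, "c"),
    M("succoa_c", "succinyl-CoA", "C25H35N7O19P3S", -5, "c"),
    M("succ_c", "succinate", "C4H4O4", -2, "c"),
    M("fum_c", "fumarate", "C4H2O4", -2, "c"),
    M("mal__L_c", "L-malate", "C4H4O5", -2, "c"),
    M("oaa_c", "oxaloacetate", "C4H2O5", -2, "c"),
    M("lac__D_c", "D-lactate", "C3H5O3", -1, "c"),
    M("ac_c", "acetate", "C2H3O2", -1, "c"),
    M("etoh_c", "ethanol", "C2H6O", 0, "c"),
    M("for_c", "formate", "CHO2", -1, "c"),
    M("alac__S_c", "(S)-2-acetolactate", "C5H7O4", -1, "c"),
    M("diact_c", "diacetyl", "C4H6O2", 0, "c"),
    M("actn__R_c", "(R)-acetoin", "C4H8O2", 0, "c"),
    M("btd_RR_c", "(R,R)-2,3-butanediol", "C4H10O2", 0, "c"),
    M("glyc_c", "glycerol", "C3H8O3", 0, "c"),
    M("glyc3p_c", "sn-glycerol 3-phosphate", "C3H7O6P", -2, "c"),
    M("dha_c", "dihydroxyacetone", "C3H6O3", 0, "c"),
    M("atp_c", "ATP", "C10H12N5O13P3", -4, "c"),
    M("adp_c", "ADP", "C10H12N5O10P2", -3, "c"),
    M("pi_c", "orthophosphate", "HO4P", -2, "c"),
    M("nad_c", "NAD+", "C21H26N7O14P2", -1, "c"),
    M("nadh_c", "NADH", "C21H27N7O14P2", -2, "c"),
    M("nadp_c", "NADP+", "C21H25N7O17P3", -3, "c"),
    M("nadph_c", "NADPH", "C21H26N7O17P3", -4, "c"),
    M("nh4_c", "ammonium", "H4N", 1, "c"),
    M("co2_c", "carbon dioxide", "CO2", 0, "c"),
    M("o2_c", "oxygen", "O2", 0, "c"),
    M("h2o_c", "water", "H2O", 0, "c"),
    M("h_c", "proton", "H", 1, "c"),
    M("ala__L_c", "L-alanine", "C3H7NO2", 0, "c"),
    M("glu__L_c", "L-glutamate", "C5H8NO4", -1, "c"),
    M("asp__L_c", "L-aspartate", "C4H6NO4", -1, "c"),
    M("gln__L_c", "L-glutamine", "C5H10N2O3", 0, "c"),
    M("amp_c", "AMP", "C10H12N5O7P", -2, "c"),
    M("gmp_c", "GMP", "C10H12N5O8P", -2, "c"),
    M("cmp_c", "CMP", "C9H12N3O8P", -2, "c"),
    M("ump_c", "UMP", "C9H11N2O9P", -2, "c"),
    M("damp_c", "dAMP", "C10H12N5O6P", -2, "c"),
    M("dgmp_c", "dGMP", "C10H12N5O7P", -2, "c"),
    M("dcmp_c", "dCMP", "C9H12N3O7P", -2, "c"),
    M("dtmp_c", "dTMP", "C10H13N2O8P", -2, "c"),
    M("hdca_c", "palmitate", "C16H31O2", -1, "c"),
    M("glycogen_c", "glycogen (glucan residue)", "C6H10O5", 0, "c")
  )
  ext <- list(
    M("glc__D_e", "D-glucose (extracellular)", "C6H12O6", 0, "e"),
    M("glyc_e", "glycerol (extracellular)", "C3H8O3", 0, "e"),
    M("o2_e", "oxygen (extracellular)", "O2", 0, "e"),
    M("co2_e", "carbon dioxide (extracellular)", "CO2", 0, "e"),
    M("nh4_e", "ammonium (extracellular)", "H4N", 1, "e"),
    M("pi_e", "orthophosphate (extracellular)", "HO4P", -2, "e"),
    M("h2o_e", "water (extracellular)", "H2O", 0, "e"),
    M("h_e", "proton (extracellular)", "H", 1, "e"),
    M("lac__D_e", "D-lactate (extracellular)", "C3H5O3", -1, "e"),
    M("ac_e", "acetate (extracellular)", "C2H3O2", -1, "e"),
    M("etoh_e", "ethanol (extracellular)", "C2H6O", 0, "e"),
    M("for_e", "formate (extracellular)", "CHO2", -1, "e"),
    M("succ_e", "succinate (extracellular)", "C4H4O4", -2, "e"),
    M("actn__R_e", "(R)-acetoin (extracellular)", "C4H8O2", 0, "e"),
    M("btd_e", "(R,R)-2,3-butanediol (extracellular)", "C4H10O2", 0, "e")
  )
  do.call(rbind, c(cyt, ext))
}

kox_reactions <- function() {
  R <- function(id, name, st, lb, ub, gpr = "", sub = "", ec = character()) {
    list(id = id, name = name, stoichiometry = st, lower_bound = lb,
         upper_bound = ub, gpr = gpr, subsystem = sub, ec_numbers = ec)
  }
  BIG <- 1000
  list(
    ## glycolysis + PTS glucose uptake
    R("GLCpts", "glucose PTS transport",
      c(glc__D_e = -1, pep_c = -1, g6p_c = 1, pyr_c = 1), 0, BIG,
      "ptsG and ptsH and ptsI", "Glycolysis", "2.7.1.199"),
    R("PGI", "glucose-6-phosphate isomerase",
      c(g6p_c = -1, f6p_c = 1), -BIG, BIG, "pgi", "Glycolysis", "5.3.1.9"),
    R("PFK", "phosphofructokinase",
      c(f6p_c = -1, atp_c = -1, fdp_c = 1, adp_c = 1, h_c = 1), 0, BIG,
      "pfkA or pfkB", "Glycolysis", "2.7.1.11"),
    R("FBA", "fructose-bisphosphate aldolase",
      c(fdp_c = -1, dhap_c = 1, g3p_c = 1), -BIG, BIG, "fbaA",
      "Glycolysis", "4.1.2.13"),
    R("TPI", "triose-phosphate isomerase",
      c(dhap_c = -1, g3p_c = 1), -BIG, BIG, "tpiA", "Glycolysis", "5.3.1.1"),
    R("GAPD_PGK", "glyceraldehyde-3P dehydrogenase + phosphoglycerate kinase",
      c(g3p_c = -1, nad_c = -1, adp_c = -1, pi_c = -1,
        `3pg_c` = 1, atp_c = 1, nadh_c = 1, h_c = 1), -BIG, BIG,
      "gapA and pgk", "Glycolysis", c("1.2.1.12", "2.7.2.3")),
    R("ENO_PGM", "phosphoglycerate mutase + enolase",
      c(`3pg_c` = -1, pep_c = 1, h2o_c = 1), -BIG, BIG, "gpmA and eno",
      "Glycolysis", c("5.4.2.11", "4.2.1.11")),
    R("PYK", "pyruvate kinase",
      c(pep_c = -1, adp_c = -1, h_c = -1, pyr_c = 1, atp_c = 1), 0, BIG,
      "pykF", "Glycolysis", "2.7.1.40"),
    R("FBP", "fructose-1,6-bisphosphatase",
      c(fdp_c = -1, h2o_c = -1, f6p_c = 1, pi_c = 1), 0, BIG,
      "fbp or glpX", "Gluconeogenesis", "3.1.3.11"),
    ## pentose phosphate shunt (lumped)
    R("G6PDH_GND", "oxidative pentose phosphate shunt (lumped)",
      c(g6p_c = -1, nadp_c = -2, h2o_c = -1,
        ru5p__D_c = 1, nadph_c = 2, co2_c = 1, h_c = 2), 0, BIG,
      "zwf and gnd", "Pentose phosphate", c("1.1.1.49", "1.1.1.44")),
    R("RPI", "ribose-5-phosphate isomerase",
      c(ru5p__D_c = -1, r5p_c = 1), -BIG, BIG, "rpiA",
      "Pentose phosphate", "5.3.1.6"),
    R("TKT_TAL", "non-oxidative pentose phosphate shunt (lumped)",
      c(ru5p__D_c = -3, f6p_c = 2, g3p_c = 1), -BIG, BIG, "tktA and talB",
      "Pentose phosphate", c("2.2.1.1", "2.2.1.2")),
    ## TCA cycle + anaplerosis
    R("CS", "citrate synthase",
      c(accoa_c = -1, oaa_c = -1, h2o_c = -1, cit_c = 1, coa_c = 1, h_c = 1),
      0, BIG, "gltA", "TCA cycle", "2.3.3.1"),
    R("ACONT", "aconitase",
      c(cit_c = -1, icit_c = 1), -BIG, BIG, "acnB", "TCA cycle", "4.2.1.3"),
    R("ICDHyr", "isocitrate dehydrogenase (NADP)",
      c(icit_c = -1, nadp_c = -1, akg_c = 1, co2_c = 1, nadph_c = 1),
      -BIG, BIG, "icd", "TCA cycle", "1.1.1.42"),
    R("AKGDH", "2-oxoglutarate dehydrogenase",
      c(akg_c = -1, coa_c = -1, nad_c = -1,
        succoa_c = 1, co2_c = 1, nadh_c = 1), 0, BIG,
      "sucA and sucB and lpd", "TCA cycle", "1.2.4.2"),
    R("SUCOAS", "succinyl-CoA synthetase",
      c(succoa_c = -1, adp_c = -1, pi_c = -1,
        succ_c = 1, coa_c = 1, atp_c = 1), -BIG, BIG, "sucC and sucD",
      "TCA cycle", "6.2.1.5"),
    R("SUCDH_OPM", "succinate dehydrogenase + oxidative phosphorylation (P/O 1)",
      c(succ_c = -1, o2_c = -0.5, adp_c = -1, pi_c = -1, h_c = -1,
        fum_c = 1, atp_c = 1, h2o_c = 2), 0, BIG,
      "sdhA and sdhB and atpA", "Energy metabolism", "1.3.5.1"),
    R("FUM", "fumarase",
      c(fum_c = -1, h2o_c = -1, mal__L_c = 1), -BIG, BIG, "fumC",
      "TCA cycle", "4.2.1.2"),
    R("MDH", "malate dehydrogenase",
      c(mal__L_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1, h_c = 1),
      -BIG, BIG, "mdh", "TCA cycle", "1.1.1.37"),
    R("PPC", "PEP carboxylase",
      c(pep_c = -1, co2_c = -1, h2o_c = -1, oaa_c = 1, pi_c = 1, h_c = 1),
      0, BIG, "ppc", "Anaplerosis", "4.1.1.31"),
    R("FRD_NADH", "fumarate reductase (NADH-linked, lumped)",
      c(fum_c = -1, nadh_c = -1, h_c = -1, succ_c = 1, nad_c = 1), 0, BIG,
      "frdA and frdB", "Fermentation", "1.3.1.6"),
    ## pyruvate node and fermentation branches
    R("PDH", "pyruvate dehydrogenase",
      c(pyr_c = -1, coa_c = -1, nad_c = -1,
        accoa_c = 1, co2_c = 1, nadh_c = 1), 0, BIG,
      "aceE and aceF and lpd", "Pyruvate metabolism", "1.2.4.1"),
    R("PFL", "pyruvate formate-lyase",
      c(pyr_c = -1, coa_c = -1, accoa_c = 1, for_c = 1), 0, BIG, "pflB",
      "Fermentation", "2.3.1.54"),
    R("LDH_D", "D-lactate dehydrogenase",
      c(pyr_c = -1, nadh_c = -1, h_c = -1, lac__D_c = 1, nad_c = 1), 0, BIG,
      "ldhA", "Fermentation", "1.1.1.28"),
    R("PTAr", "phosphotransacetylase",
      c(accoa_c = -1, pi_c = -1, actp_c = 1, coa_c = 1), -BIG, BIG,
      "pta or eutD", "Fermentation", "2.3.1.8"),
    R("ACKr", "acetate kinase",
      c(actp_c = -1, adp_c = -1, ac_c = 1, atp_c = 1), -BIG, BIG,
      "ackA or tdcD", "Fermentation", "2.7.2.1"),
    R("ALCD_ADH", "acetaldehyde/alcohol dehydrogenase (lumped)",
      c(accoa_c = -1, nadh_c = -2, h_c = -2,
        etoh_c = 1, coa_c = 1, nad_c = 2), 0, BIG, "adhE",
      "Fermentation", c("1.2.1.10", "1.1.1.1")),
    ## 2,3-butanediol pathway
    R("ACLS", "acetolactate synthase",
      c(pyr_c = -2, h_c = -1, alac__S_c = 1, co2_c = 1), 0, BIG, "budB",
      "Butanediol pathway", "2.2.1.6"),
    R("ACLDC", "acetolactate decarboxylase",
      c(alac__S_c = -1, h_c = -1, actn__R_c = 1, co2_c = 1), 0, BIG, "budA",
      "Butanediol pathway", "4.1.1.5"),
    R("BTDD_RR", "acetoin reductase / 2,3-butanediol dehydrogenase",
      c(actn__R_c = -1, nadh_c = -1, h_c = -1, btd_RR_c = 1, nad_c = 1),
      0, BIG, "budC", "Butanediol pathway", "1.1.1.4"),
    R("ACLS_SPONT", "spontaneous oxidative acetolactate decarboxylation",
      c(alac__S_c = -1, o2_c = -0.5, h_c = -1,
        diact_c = 1, co2_c = 1, h2o_c = 1), 0, BIG, "",
      "Butanediol pathway", character()),
    R("DAR", "diacetyl reductase",
      c(diact_c = -1, nadh_c = -1, h_c = -1, actn__R_c = 1, nad_c = 1),
      0, BIG, "dar", "Butanediol pathway", "1.1.1.303"),
    ## glycerol utilization, oxidative and reductive routes
    R("GLYK", "glycerol kinase",
      c(glyc_c = -1, atp_c = -1, glyc3p_c = 1, adp_c = 1, h_c = 1), 0, BIG,
      "glpK", "Glycerol metabolism", "2.7.1.30"),
    R("G3PD_OPM", "glycerol-3-phosphate dehydrogenase + oxidative phosphorylation (P/O 1)",
      c(glyc3p_c = -1, o2_c = -0.5, adp_c = -1, pi_c = -1, h_c = -1,
        dhap_c = 1, atp_c = 1, h2o_c = 2), 0, BIG, "glpD",
      "Glycerol metabolism", "1.1.5.3"),
    R("GLYCDH", "NAD-dependent glycerol dehydrogenase",
      c(glyc_c = -1, nad_c = -1, dha_c = 1, nadh_c = 1, h_c = 1), 0, BIG,
      "gldA", "Glycerol metabolism", "1.1.1.6"),
    R("DHAK", "dihydroxyacetone kinase",
      c(dha_c = -1, atp_c = -1, dhap_c = 1, adp_c = 1, h_c = 1), 0, BIG,
      "dhaK", "Glycerol metabolism", "2.7.1.29"),
    ## respiration and redox housekeeping
    R("NADH_OPM", "NADH dehydrogenase + oxidative phosphorylation (P/O 2)",
      c(nadh_c = -1, o2_c = -0.5, h_c = -3, adp_c = -2, pi_c = -2,
        nad_c = 1, atp_c = 2, h2o_c = 3), 0, BIG,
      "nuoB and cyoB and atpA", "Energy metabolism", "1.6.5.3"),
    R("THD", "membrane transhydrogenase (NADPH-forming)",
      c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1), 0, BIG,
      "pntA and pntB", "Energy metabolism", "1.6.1.2"),
    R("STH", "soluble transhydrogenase (NADH-forming)",
      c(nadph_c = -1, nad_c = -1, nadp_c = 1, nadh_c = 1), 0, BIG,
      "sthA", "Energy metabolism", "1.6.1.1"),
    ## lumped monomer biosynthesis
    R("GDH", "glutamate dehydrogenase (NADPH)",
      c(akg_c = -1, nh4_c = -1, nadph_c = -1, h_c = -1,
        glu__L_c = 1, h2o_c = 1, nadp_c = 1), 0, BIG, "gdhA",
      "Amino acid biosynthesis", "1.4.1.4"),
    R("ALATA", "alanine transaminase",
      c(pyr_c = -1, glu__L_c = -1, ala__L_c = 1, akg_c = 1), 0, BIG, "alaC",
      "Amino acid biosynthesis", "2.6.1.2"),
    R("ASPTA", "aspartate transaminase",
      c(oaa_c = -1, glu__L_c = -1, asp__L_c = 1, akg_c = 1), 0, BIG, "aspC",
      "Amino acid biosynthesis", "2.6.1.1"),
    R("GLNS", "glutamine synthetase",
      c(glu__L_c = -1, nh4_c = -1, atp_c = -1,
        gln__L_c = 1, adp_c = 1, pi_c = 1, h_c = 1), 0, BIG, "glnA",
      "Amino acid biosynthesis", "6.3.1.2"),
    R("AMPSYN", "AMP de novo biosynthesis (lumped)",
      c(r5p_c = -1, nh4_c = -5, co2_c = -1, for_c = -4, nadh_c = -1,
        atp_c = -7,
        amp_c = 1, nad_c = 1, adp_c = 7, pi_c = 7, h2o_c = 4, h_c = 7),
      0, BIG, "purF", "Nucleotide biosynthesis", character()),
    R("GMPSYN", "GMP de novo biosynthesis (lumped)",
      c(r5p_c = -1, nh4_c = -5, co2_c = -1, for_c = -4, atp_c = -8,
        gmp_c = 1, adp_c = 8, pi_c = 8, h2o_c = 2, h_c = 9),
      0, BIG, "guaA", "Nucleotide biosynthesis", character()),
    R("UMPSYN", "UMP de novo biosynthesis (lumped)",
      c(r5p_c = -1, nh4_c = -2, co2_c = -2, for_c = -2, nadh_c = -3,
        atp_c = -4,
        ump_c = 1, nad_c = 3, adp_c = 4, pi_c = 4, h2o_c = 3, h_c = 1),
      0, BIG, "pyrF", "Nucleotide biosynthesis", character()),
    R("CMPSYN", "CMP de novo biosynthesis (lumped)",
      c(r5p_c = -1, nh4_c = -3, co2_c = -2, for_c = -2, nadh_c = -3,
        atp_c = -5,
        cmp_c = 1, nad_c = 3, adp_c = 5, pi_c = 5, h2o_c = 3, h_c = 3),
      0, BIG, "pyrG", "Nucleotide biosynthesis", character()),
    R("DAMPSYN", "dAMP biosynthesis (ribonucleotide reduction, lumped)",
      c(amp_c = -1, nadph_c = -1, h_c = -1,
        damp_c = 1, nadp_c = 1, h2o_c = 1), 0, BIG, "nrdA and nrdB",
      "Nucleotide biosynthesis", "1.17.4.1"),
    R("DGMPSYN", "dGMP biosynthesis (ribonucleotide reduction, lumped)",
      c(gmp_c = -1, nadph_c = -1, h_c = -1,
        dgmp_c = 1, nadp_c = 1, h2o_c = 1), 0, BIG, "nrdA and nrdB",
      "Nucleotide biosynthesis", "1.17.4.1"),
    R("DCMPSYN", "dCMP biosynthesis (ribonucleotide reduction, lumped)",
      c(cmp_c = -1, nadph_c = -1, h_c = -1,
        dcmp_c = 1, nadp_c = 1, h2o_c = 1), 0, BIG, "nrdA and nrdB",
      "Nucleotide biosynthesis", "1.17.4.1"),
    R("DTMPSYN", "dTMP biosynthesis (reduction + methylation, lumped)",
      c(ump_c = -1, for_c = -1, nadph_c = -3, h_c = -4,
        dtmp_c = 1, nadp_c = 3, h2o_c = 3), 0, BIG,
      "nrdA and nrdB and thyA", "Nucleotide biosynthesis", character()),
    R("FASYN", "palmitate biosynthesis (lumped)",
      c(accoa_c = -8, atp_c = -7, nadph_c = -14, h_c = -6, h2o_c = -1,
        hdca_c = 1, coa_c = 8, adp_c = 7, pi_c = 7, nadp_c = 14), 0, BIG,
      "accA and fabB and fabD", "Lipid biosynthesis", character()),
    R("GLYCOGENSYN", "glycogen synthesis (lumped)",
      c(g6p_c = -1, atp_c = -1, h2o_c = -1,
        glycogen_c = 1, adp_c = 1, pi_c = 2, h_c = 1), 0, BIG,
      "glgA and glgC", "Carbohydrate biosynthesis", "2.4.1.21"),
    ## transport
    R("O2t", "oxygen diffusion", c(o2_e = -1, o2_c = 1), -BIG, BIG, "",
      "Transport"),
    R("CO2t", "CO2 diffusion", c(co2_e = -1, co2_c = 1), -BIG, BIG, "",
      "Transport"),
    R("H2Ot", "water diffusion", c(h2o_e = -1, h2o_c = 1), -BIG, BIG, "",
      "Transport"),
    R("Ht", "proton exchange (lumped)", c(h_e = -1, h_c = 1), -BIG, BIG, "",
      "Transport"),
    R("NH4t", "ammonium transport", c(nh4_e = -1, nh4_c = 1), -BIG, BIG,
      "amtB", "Transport"),
    R("PIt", "phosphate transport", c(pi_e = -1, pi_c = 1), -BIG, BIG,
      "pitA", "Transport"),
    R("GLYCt", "glycerol facilitator", c(glyc_e = -1, glyc_c = 1),
      -BIG, BIG, "glpF", "Transport"),
    R("LACt", "D-lactate efflux", c(lac__D_c = -1, lac__D_e = 1), 0, BIG,
      "", "Transport"),
    R("ACt", "acetate efflux", c(ac_c = -1, ac_e = 1), 0, BIG, "",
      "Transport"),
    R("ETOHt", "ethanol efflux", c(etoh_c = -1, etoh_e = 1), 0, BIG, "",
      "Transport"),
    R("FORt", "formate efflux", c(for_c = -1, for_e = 1), 0, BIG, "",
      "Transport"),
    R("SUCCt", "succinate efflux", c(succ_c = -1, succ_e = 1), 0, BIG, "",
      "Transport"),
    R("ACTNt", "acetoin efflux", c(actn__R_c = -1, actn__R_e = 1), 0, BIG,
      "", "Transport"),
    R("BTDt", "2,3-butanediol efflux", c(btd_RR_c = -1, btd_e = 1), 0, BIG,
      "", "Transport"),
    ## exchanges (bounds set by the medium)
    R("EX_glc__D_e", "glucose exchange", c(glc__D_e = -1), 0, 0),
    R("EX_glyc_e", "glycerol exchange", c(glyc_e = -1), 0, 0),
    R("EX_o2_e", "oxygen exchange", c(o2_e = -1), 0, 0),
    R("EX_co2_e", "CO2 exchange", c(co2_e = -1), -BIG, BIG),
    R("EX_nh4_e", "ammonium exchange", c(nh4_e = -1), -BIG, BIG),
    R("EX_pi_e", "phosphate exchange", c(pi_e = -1), -BIG, BIG),
    R("EX_h2o_e", "water exchange", c(h2o_e = -1), -BIG, BIG),
    R("EX_h_e", "proton exchange", c(h_e = -1), -BIG, BIG),
    R("EX_lac__D_e", "D-lactate exchange", c(lac__D_e = -1), 0, BIG),
    R("EX_ac_e", "acetate exchange", c(ac_e = -1), 0, BIG),
    R("EX_etoh_e", "ethanol exchange", c(etoh_e = -1), 0, BIG),
    R("EX_for_e", "formate exchange", c(for_e = -1), 0, BIG),
    R("EX_succ_e", "succinate exchange", c(succ_e = -1), 0, BIG),
    R("EX_actn__R_e", "acetoin exchange", c(actn__R_e = -1), 0, BIG),
    R("EX_btd_e", "2,3-butanediol exchange", c(btd_e = -1), 0, BIG)
  )
}

kox_genes <- function() {
  sort(unique(c(
    "ptsG", "ptsH", "ptsI", "pgi", "pfkA", "pfkB", "fbp", "glpX", "fbaA",
    "tpiA", "gapA", "tdcD", "eutD",
    "pgk", "gpmA", "eno", "pykF", "zwf", "gnd", "rpiA", "tktA", "talB",
    "gltA", "acnB", "icd", "sucA", "sucB", "sucC", "sucD", "lpd", "sdhA",
    "sdhB", "fumC", "mdh", "ppc", "frdA", "frdB", "aceE", "aceF", "ldhA",
    "pflB", "pta", "ackA", "adhE", "budB", "budA", "budC", "dar", "glpK",
    "glpD", "gldA", "dhaK", "nuoB", "cyoB", "atpA", "pntA", "pntB", "gdhA",
    "sthA", "alaC", "aspC", "glnA", "purF", "guaA", "pyrF", "pyrG", "nrdA", "nrdB",
    "thyA", "accA", "fabB", "fabD", "glgA", "glgC", "amtB", "pitA", "glpF"
  )))
}

#' Fixture manifest: reactions, EC numbers, gene rules and bounds
#'
#' @param model A model from [build_core_model()] (or any `cb_model`).
#' @return `data.frame` with one row per reaction: `id`, `name`,
#'   `ec_numbers` (comma-joined), `gpr`, `subsystem`, `lower_bound`,
#'   `upper_bound`, `is_exchange`.
#' @export
fixture_manifest <- function(model) {
  do.call(rbind, lapply(model$reactions, function(r) {
    data.frame(id = r$id, name = r$name,
               ec_numbers = paste(r$ec_numbers, collapse = ","),
               gpr = r$gpr, subsystem = r$subsystem,
               lower_bound = r$lower_bound, upper_bound = r$upper_bound,
               is_exchange = r$is_exchange, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
}

#' Net stoichiometry of a reaction set
#'
#' Sums the stoichiometries of the listed reactions (optionally weighted),
#' drops intermediates that cancel, and rescales so the reference metabolite
#' has coefficient of magnitude 1 (sign preserved). Used e.g. to verify
#' that the three-step budB/budA/budC route releases 2 CO2 and oxidizes
#' 1 NADH per 2,3-BD formed from pyruvate.
#'
#' @param model A `cb_model`.
#' @param reaction_ids Reactions to lump.
#' @param normalize_to Metabolite id that must survive in the net result.
#' @param weights Optional numeric weights (flux ratios) aligned with
#'   `reaction_ids`; default all 1.
#' @param tol Coefficients with `|coef| < tol` are treated as cancelled.
#' @return Named numeric of net coefficients (negative = consumed).
#' @examples
#' \donttest{
#' m <- build_core_model()
#' net_stoichiometry(m, c("ACLS", "ACLDC", "BTDD_RR"), "btd_RR_c")
#' }
#' @export
net_stoichiometry <- function(model, reaction_ids, normalize_to,
                              weights = NULL, tol = 1e-9) {
  if (length(reaction_ids) == 0L) {
    stop("empty reaction list: normalization target absent", call. = FALSE)
  }
  missing <- setdiff(reaction_ids, names(model$reactions))
  if (length(missing) > 0L) {
    stop("unknown reactions: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(reaction_ids))
  stopifnot(length(weights) == length(reaction_ids))
  net <- numeric()
  for (k in seq_along(reaction_ids)) {
    st <- model$reactions[[reaction_ids[k]]]$stoichiometry * weights[k]
    for (m in names(st)) {
      net[m] <- (if (m %in% names(net)) net[m] else 0) + st[[m]]
    }
  }
  net <- net[abs(net) > tol]
  if (!normalize_to %in% names(net)) {
    stop("normalization target '", normalize_to,
         "' cancels out of the net stoichiometry", call. = FALSE)
  }
  net / abs(net[[normalize_to]])
}

#' Deterministically perturb non-exchange reaction bounds
#'
#' Property-test input generator: scales the bounds of randomly chosen
#' non-exchange reactions by factors in `(1 - magnitude, 1 + magnitude)`.
#' Scaling preserves signs, so reversibility is never flipped, and
#' stoichiometry is untouched (mass balance is invariant). Deterministic
#' for a given seed.
#'
#' @param model A `cb_model`.
#' @param seed Integer seed.
#' @param magnitude Fraction in (0, 1).
#' @return The perturbed model.
#' @export
perturb_bounds <- function(model, seed, magnitude = 0.2) {
  if (magnitude <= 0 || magnitude >= 1) {
    stop("magnitude must lie in (0, 1)", call. = FALSE)
  }
  rng <- local({
    set.seed(seed)
    n <- length(model$reactions)
    list(pick = stats::runif(n) < 0.5,
         fac = 1 + stats::runif(n, -magnitude, magnitude))
  })
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    if (r$is_exchange || !rng$pick[j]) next
    r$lower_bound <- r$lower_bound * rng$fac[j]
    r$upper_bound <- r$upper_bound * rng$fac[j]
    model$reactions[[j]] <- r
  }
  model
}
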