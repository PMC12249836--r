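# Synthetic test bed: a lumped astrocyte metabolic network with analytically
# known optima, plus a planted-effect proteomics generator.
#
# The toy network covers the pathways a cortical astrocyte model is expected
# to exhibit -- glycolysis with lactate release, glycogen synthesis and
# phosphorolysis, the oxidative pentose phosphate branch, pyruvate
# dehydrogenase and a lumped TCA cycle, NADH/FADH2-oxidizing oxidative
# phosphorylation, a malate-aspartate NADH shuttle, ketone-body handling,
# carnitine-shuttled beta-oxidation, the glutamate-glutamine cycle, and an
# acid-handling block (Na+/H+ exchange plus the CO2/bicarbonate system) --
# at a scale where optimal fluxes can be derived by hand.

#' Parameters of the toy astrocyte model
#'
#' @param include_glycogen_turnover force a small positive lower bound
#'   (0.001 µmol/g/min) on glycogen synthase, glycogen phosphorylase, the
#'   fructose-2,6-bisphosphate-forming reaction and lactate dehydrogenase,
#'   so that the futile storage/mobilization cycle, the glycolytic regulator
#'   and baseline lactate release are visibly active at the parsimonious
#'   optimum (a fixture device for the physiology checks, not a biological
#'   claim: an ATP-maximizing lumped network would otherwise shuttle every
#'   cytosolic NADH instead of reducing pyruvate).
#' @param atp_per_nadh,atp_per_fadh2 lumped P/O ratios (textbook consensus
#'   2.5 and 1.5 ATP per NADH / FADH2).
#' @param substrate_level_atp_per_glc net substrate-level ATP per glucose
#'   through lumped glycolysis (2).
#' @param glc_rate,o2_rate,co2_rate,glu_rate,gln_rate,acac_rate,lnlc_rate
#'   physiological exchange-rate magnitudes (µmol/g/min) baked into the
#'   default bounds: glucose and oxygen uptake, CO2 release, glutamate
#'   uptake, glutamine release, acetoacetate uptake, linoleate uptake.
#' @param nhe_capacity,hco3_capacity baseline capacities of the Na+/H+
#'   exchanger and the bicarbonate importer (µmol/g/min); chosen so proton
#'   export does not bind under baseline conditions but a halved buffering
#'   capacity does.
#' @param atp_demand optional fixed ATP-maintenance demand; when set, the
#'   ATP maintenance reaction is pinned to `lb = ub = atp_demand` so
#'   condition comparisons are demand-driven rather than capacity-driven.
#' @return list of class `"toy_model_spec"`.
#' @export
toy_model_spec <- function(include_glycogen_turnover = FALSE,
                           atp_per_nadh = 2.5, atp_per_fadh2 = 1.5,
                           substrate_level_atp_per_glc = 2,
                           glc_rate = 0.19, o2_rate = 0.530,
                           co2_rate = 0.515, glu_rate = 0.232,
                           gln_rate = 0.5, acac_rate = 0.012,
                           lnlc_rate = 0.0011,
                           nhe_capacity = 0.6, hco3_capacity = 0.6,
                           atp_demand = NULL) {
  structure(as.list(environment()), class = "toy_model_spec")
}

#' Generate the toy astrocyte model
#'
#' Deterministically builds the lumped astrocyte network described in
#' [toy_model_spec()]. The generated model passes [validate_model()] with no
#' violations, and its optimal ATP-maintenance objective has closed forms
#' under anaerobic, hypoxic and aerobic bounds (see [analytic_toy_fluxes()]).
#' GPR rules carry the enzyme symbols used by the proteomics integration
#' (PYGB, PKM, PDHA1, NDUFA11, SDHA, CPT2, G6PD, PGM2, HEXA, ...).
#'
#' @param spec a [toy_model_spec()].
#' @return a validated `metabolic_model` whose default objective maximizes
#'   ATP maintenance first and glutamate-to-glutamine cycling second.
#' @export
generate_toy_astrocyte_model <- function(spec = toy_model_spec()) {
  stopifnot(inherits(spec, "toy_model_spec"))
  a <- spec$atp_per_nadh; f <- spec$atp_per_fadh2
  slp <- spec$substrate_level_atp_per_glc
  glyc_lb <- if (spec$include_glycogen_turnover) 0.001 else 0

  met <- function(id, name, compartment) {
    data.frame(id = id, name = name, compartment = compartment,
               formula = NA_character_, stringsAsFactors = FALSE)
  }
  mets <- rbind(
    met("glc_e", "glucose", "e"),        met("glc_c", "glucose", "c"),
    met("o2_e", "oxygen", "e"),          met("o2_c", "oxygen", "c"),
    met("co2_e", "carbon dioxide", "e"), met("co2_c", "carbon dioxide", "c"),
    met("co2_m", "carbon dioxide", "m"),
    met("lac_e", "L-lactate", "e"),      met("lac_c", "L-lactate", "c"),
    met("pyr_e", "pyruvate", "e"),       met("pyr_c", "pyruvate", "c"),
    met("glu_e", "glutamate", "e"),      met("glu_c", "glutamate", "c"),
    met("gln_e", "glutamine", "e"),      met("gln_c", "glutamine", "c"),
    met("acac_e", "acetoacetate", "e"),  met("acac_c", "acetoacetate", "c"),
    met("acac_m", "acetoacetate", "m"),  met("accoa_m", "acetyl-CoA", "m"),
    met("nad_c", "NAD+", "c"),           met("nadh_c", "NADH", "c"),
    met("nad_m", "NAD+", "m"),           met("nadh_m", "NADH", "m"),
    met("fad_m", "FAD", "m"),            met("fadh2_m", "FADH2", "m"),
    met("adp_c", "ADP", "c"),            met("atp_c", "ATP", "c"),
    met("adp_m", "ADP", "m"),            met("atp_m", "ATP", "m"),
    met("pi_e", "phosphate", "e"),       met("pi_c", "phosphate", "c"),
    met("pi_m", "phosphate", "m"),
    met("h_e", "proton", "e"),           met("h_c", "proton", "c"),
    met("hco3_e", "bicarbonate", "e"),   met("hco3_c", "bicarbonate", "c"),
    met("h2o_e", "water", "e"),          met("h2o_c", "water", "c"),
    met("lnlc_e", "linoleate", "e"),     met("lnlc_c", "linoleate", "c"),
    met("facoa_c", "fatty acyl-CoA", "c"), met("facoa_m", "fatty acyl-CoA", "m"),
    met("glycogen_c", "glycogen", "c"),
    met("r5p_c", "ribose-5-phosphate", "c"),
    met("r1p_c", "ribose-1-phosphate", "c"),
    met("f26bp_c", "fructose-2,6-bisphosphate", "c"),
    met("nadp_c", "NADP+", "c"),         met("nadph_c", "NADPH", "c"),
    met("gsl_e", "glycosphingolipid", "e"),
    met("gsl_c", "glycosphingolipid", "c"),
    met("glcnac_c", "N-acetylglucosamine", "c")
  )

  rx_rows <- list(); sto <- list()
  rxn <- function(id, name, sto_vec, lb, ub, subsystem, gpr = "") {
    rx_rows[[length(rx_rows) + 1L]] <<- data.frame(
      id = id, name = name, lower_bound = lb, upper_bound = ub,
      subsystem = subsystem, gpr = gpr, stringsAsFactors = FALSE)
    sto[[id]] <<- sto_vec
  }
  B <- DEFAULT_BOUND

  ## exchanges (negative flux = uptake)
  rxn("EX_glc_e", "glucose exchange", c(glc_e = -1), -spec$glc_rate, 0,
      "Transport/Exchange")
  rxn("EX_o2_e", "oxygen exchange", c(o2_e = -1), -spec$o2_rate, 0,
      "Transport/Exchange")
  rxn("EX_co2_e", "carbon dioxide exchange", c(co2_e = -1), 0, spec$co2_rate,
      "Transport/Exchange")
  rxn("EX_lac_e", "L-lactate exchange", c(lac_e = -1), 0, B,
      "Transport/Exchange")
  rxn("EX_glu_e", "glutamate exchange", c(glu_e = -1), -spec$glu_rate, 0,
      "Transport/Exchange")
  rxn("EX_gln_e", "glutamine exchange", c(gln_e = -1), 0, spec$gln_rate,
      "Transport/Exchange")
  rxn("EX_acac_e", "acetoacetate exchange", c(acac_e = -1), -spec$acac_rate, B,
      "Transport/Exchange")
  rxn("EX_pyr_e", "pyruvate exchange", c(pyr_e = -1), 0, B,
      "Transport/Exchange")
  rxn("EX_lnlc_e", "linoleate exchange", c(lnlc_e = -1), -spec$lnlc_rate, 0,
      "Transport/Exchange")
  rxn("EX_h_e", "proton exchange", c(h_e = -1), 0, B, "Transport/Exchange")
  rxn("EX_hco3_e", "bicarbonate exchange", c(hco3_e = -1), -B, 0,
      "Transport/Exchange")
  rxn("EX_h2o_e", "water exchange", c(h2o_e = -1), -B, B, "Transport/Exchange")
  rxn("EX_pi_e", "phosphate exchange", c(pi_e = -1), -B, B,
      "Transport/Exchange")
  rxn("EX_gsl_e", "glycosphingolipid exchange", c(gsl_e = -1), -0.001, 0,
      "Transport/Exchange")

  ## transporters
  rxn("GLCt", "glucose transport", c(glc_e = -1, glc_c = 1), 0, B,
      "Transport/Exchange", "SLC2A1")
  rxn("O2t", "oxygen diffusion", c(o2_e = -1, o2_c = 1), 0, B,
      "Transport/Exchange")
  rxn("CO2tm", "mitochondrial CO2 diffusion", c(co2_m = -1, co2_c = 1), 0, B,
      "Transport/Exchange")
  rxn("CO2t", "CO2 release", c(co2_c = -1, co2_e = 1), 0, B,
      "Transport/Exchange")
  rxn("LACt", "lactate export (MCT)", c(lac_c = -1, lac_e = 1), 0, B,
      "Transport/Exchange", "SLC16A1")
  rxn("PYRt", "pyruvate export", c(pyr_c = -1, pyr_e = 1), 0, B,
      "Transport/Exchange")
  rxn("GLUt", "glutamate uptake (EAAT1)", c(glu_e = -1, glu_c = 1), 0, B,
      "Glutamate/Glutamine", "SLC1A3")
  rxn("GLNt", "glutamine export (SNAT3)", c(gln_c = -1, gln_e = 1), 0, B,
      "Glutamate/Glutamine", "SLC38A3")
  rxn("ACACt", "acetoacetate transport", c(acac_e = -1, acac_c = 1), -B, B,
      "Transport/Exchange")
  rxn("LACACACt", "lactate/acetoacetate antiport",
      c(lac_c = -1, acac_e = -1, lac_e = 1, acac_c = 1), 0, B,
      "Transport/Exchange")
  rxn("ACACtm", "mitochondrial acetoacetate transport",
      c(acac_c = -1, acac_m = 1), -B, B, "Ketone metabolism")
  rxn("LNLCt", "linoleate uptake", c(lnlc_e = -1, lnlc_c = 1), 0, B,
      "Transport/Exchange", "FABP5")
  rxn("HCO3t", "bicarbonate import (NBC)", c(hco3_e = -1, hco3_c = 1), 0,
      spec$hco3_capacity, "Acid-base", "SLC4A4")
  rxn("NHE", "Na+/H+ exchanger (lumped Na recycling)", c(h_c = -1, h_e = 1),
      0, spec$nhe_capacity, "Acid-base", "SLC9A1")
  rxn("H2Ot", "water diffusion", c(h2o_e = -1, h2o_c = 1), -B, B,
      "Transport/Exchange")
  rxn("PIt_e", "phosphate import", c(pi_e = -1, pi_c = 1), -B, B,
      "Transport/Exchange")
  rxn("PIt", "mitochondrial phosphate carrier", c(pi_c = -1, pi_m = 1), 0, B,
      "Transport/Exchange")
  rxn("ANT", "adenine nucleotide translocase",
      c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1), 0, B,
      "OxPhos", "SLC25A4")
  rxn("MAS", "malate-aspartate NADH shuttle",
      c(nadh_c = -1, nad_m = -1, nad_c = 1, nadh_m = 1), 0, B,
      "Transport/Exchange", "MDH1 and GOT1")
  rxn("GSLt", "glycosphingolipid uptake", c(gsl_e = -1, gsl_c = 1), 0, B,
      "Glycosphingolipid")

  ## core metabolism
  glyc_sto <- c(glc_c = -1, nad_c = -2, pyr_c = 2, nadh_c = 2)
  glyc_sto <- c(glyc_sto, adp_c = -slp, pi_c = -slp, atp_c = slp)
  rxn("GLYC", "glycolysis (lumped)", glyc_sto, 0, B, "Glycolysis",
      "HK1 and PFKL and PKM")
  rxn("LDH", "lactate dehydrogenase",
      c(pyr_c = -1, nadh_c = -1, lac_c = 1, nad_c = 1, h_c = 1),
      if (spec$include_glycogen_turnover) glyc_lb else -B, B,
      "Glycolysis", "LDHA")
  rxn("PFKFB", "fructose-2,6-bisphosphate formation",
      c(glc_c = -1, atp_c = -1, f26bp_c = 1, adp_c = 1), glyc_lb, B,
      "Glycolysis", "PFKFB3")
  rxn("PDH", "pyruvate dehydrogenase",
      c(pyr_c = -1, nad_m = -1, accoa_m = 1, nadh_m = 1, co2_m = 1), 0, B,
      "TCA", "PDHA1 and PDHB and DLAT")
  rxn("TCA", "TCA cycle (lumped)",
      c(accoa_m = -1, nad_m = -3, fad_m = -1, adp_m = -1, pi_m = -1,
        nadh_m = 3, fadh2_m = 1, atp_m = 1, co2_m = 2), 0, B,
      "TCA", "CS and IDH2 and MDH2")
  rxn("OXPHOS_NADH", "oxidative phosphorylation, NADH branch",
      c(nadh_m = -1, o2_c = -0.5, adp_m = -a, pi_m = -a,
        nad_m = 1, atp_m = a, h2o_c = 1), 0, B,
      "OxPhos", "NDUFA11 and NDUFA9 and UQCRC1 and COX4I1 and ATP5F1A")
  rxn("OXPHOS_FADH2", "oxidative phosphorylation, FADH2 branch",
      c(fadh2_m = -1, o2_c = -0.5, adp_m = -f, pi_m = -f,
        fad_m = 1, atp_m = f, h2o_c = 1), 0, B,
      "OxPhos", "SDHA and UQCRC1 and COX4I1 and ATP5F1A")
  atpm_lb <- if (is.null(spec$atp_demand)) 0 else spec$atp_demand
  atpm_ub <- if (is.null(spec$atp_demand)) B else spec$atp_demand
  rxn("ATPM", "ATP maintenance",
      c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1), atpm_lb, atpm_ub,
      "ATP maintenance")
  rxn("GLNS", "glutamine synthesis (lumped)", c(glu_c = -1, gln_c = 1), 0, B,
      "Glutamate/Glutamine", "GLUL")
  rxn("GS", "glycogen synthase (lumped)",
      c(glc_c = -1, atp_c = -1, glycogen_c = 1, adp_c = 1, pi_c = 1),
      glyc_lb, B, "Glycogen", "GYS1")
  rxn("GP", "glycogen phosphorylase", c(glycogen_c = -1, glc_c = 1),
      glyc_lb, B, "Glycogen", "PYGB")
  rxn("PPP", "oxidative pentose phosphate branch (lumped)",
      c(glc_c = -1, atp_c = -1, nadp_c = -2,
        r5p_c = 1, nadph_c = 2, co2_c = 1, adp_c = 1), 0, B,
      "PPP", "G6PD and PGD")
  rxn("PGM2", "phosphoglucomutase 2 (R1P <-> R5P)",
      c(r1p_c = -1, r5p_c = 1), -B, B, "PPP", "PGM2")
  rxn("SK_r1p", "ribose-1-phosphate salvage pool", c(r1p_c = -1), -0.01, B,
      "Demand")
  rxn("DM_r5p", "ribose-5-phosphate demand", c(r5p_c = -1), 0, B, "Demand")
  rxn("DM_f26bp", "fructose-2,6-bisphosphate turnover", c(f26bp_c = -1), 0, B,
      "Demand")
  rxn("NADPHD", "NADPH demand (antioxidant defense)",
      c(nadph_c = -1, nadp_c = 1), 0, B, "Demand")
  rxn("KETOGEN", "ketogenesis (lumped)", c(accoa_m = -2, acac_m = 1), 0, B,
      "Ketone metabolism", "HMGCS2 and HMGCL")
  rxn("KETOLYS", "ketolysis (lumped)", c(acac_m = -1, accoa_m = 2), 0, B,
      "Ketone metabolism", "OXCT1")
  rxn("ACS", "fatty acid activation",
      c(lnlc_c = -1, atp_c = -2, facoa_c = 1, adp_c = 2, pi_c = 2), 0, B,
      "Beta-oxidation", "ACSL1")
  rxn("CPT2r", "carnitine shuttle", c(facoa_c = -1, facoa_m = 1), 0, B,
      "Carnitine shuttle", "CPT1A and CPT2")
  rxn("BOX", "beta-oxidation (lumped)",
      c(facoa_m = -1, nad_m = -7, fad_m = -7,
        accoa_m = 8, nadh_m = 7, fadh2_m = 7), 0, B,
      "Beta-oxidation", "ACADVL and ECHS1 and HADHA")
  rxn("BUF", "bicarbonate buffering of cytosolic acid",
      c(h_c = -1, hco3_c = -1, co2_c = 1, h2o_c = 1), 0, B,
      "Acid-base", "CA2")
  rxn("HEXA_R", "glycosphingolipid degradation (hexosaminidase)",
      c(gsl_c = -1, glcnac_c = 1), 0, B, "Glycosphingolipid", "HEXA and HEXB")
  rxn("DM_glcnac", "N-acetylglucosamine demand", c(glcnac_c = -1), 0, B,
      "Demand")

  rxns <- do.call(rbind, rx_rows)
  obj <- objective_spec(
    objective_tier(c(ATPM = 1), "max"),
    objective_tier(c(GLNS = 1), "max")
  )
  metabolic_model(mets, rxns, sto,
                  compartments = c(c = "cytosol", m = "mitochondrion",
                                   e = "extracellular"),
                  objective = obj)
}

#' Closed-form optima of the toy astrocyte model
#'
#' Expected tier-1 (ATP maintenance) optimum and forced marker fluxes for
#' named bound scenarios of the default toy model, derived by hand from the
#' lumped stoichiometry:
#'
#' * `anaerobic` (oxygen exchange closed): all ATP is glycolytic, objective
#'   `2 * 0.19 = 0.38`; pyruvate and NADH are disposed 1:1 through lactate
#'   dehydrogenase, so lactate release is `0.38`.
#' * `hypoxia` (oxygen uptake scaled to 2 %): every marginal use of O2 --
#'   shuttled cytosolic NADH, pyruvate dehydrogenase, or the full TCA
#'   package -- yields 5 ATP per O2 at the default P/O ratios, so the
#'   objective is `0.38 + 5 * (0.02 * 0.530) = 0.433`.
#' * `aerobic` (default bounds): every oxygen-using route tied to glucose
#'   (shuttled cytosolic NADH, pyruvate dehydrogenase, the TCA package)
#'   yields 5 ATP per O2, beta-oxidation less (26/7), and the CO2-release
#'   cap is slack because carbon can leave as pyruvate or ketone bodies
#'   while its electrons are retained; the optimum is therefore oxygen
#'   limited at `0.38 + 5 * 0.530 = 3.03`, with oxygen uptake pinned at
#'   `0.530`.
#'
#' These closed forms hold for the default lumped yields (P/O 2.5 / 1.5,
#' 2 substrate-level ATP per glucose); the function refuses other yields
#' rather than report a stale formula.
#'
#' @param scenario `"aerobic"`, `"anaerobic"` or `"hypoxia"`.
#' @param spec a [toy_model_spec()] (default yields required).
#' @param o2_fraction hypoxic oxygen fraction (default 0.02).
#' @return list with `objective` and named `markers` (reaction id ->
#'   expected flux; exchange fluxes signed, negative = uptake).
#' @export
analytic_toy_fluxes <- function(scenario = c("aerobic", "anaerobic",
                                             "hypoxia"),
                                spec = toy_model_spec(), o2_fraction = 0.02) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(spec, "toy_model_spec"))
  if (spec$atp_per_nadh != 2.5 || spec$atp_per_fadh2 != 1.5 ||
      spec$substrate_level_atp_per_glc != 2) {
    stop("closed forms are derived for the default lumped yields ",
         "(atp_per_nadh 2.5, atp_per_fadh2 1.5, 2 substrate-level ATP/glc)",
         call. = FALSE)
  }
  slp_total <- 2 * spec$glc_rate
  atp_per_o2 <- 5   # 2 NADH/O2 * 2.5; equals the TCA package yield
  switch(scenario,
    anaerobic = list(
      objective = slp_total,
      markers = c(GLYC = spec$glc_rate, EX_lac_e = 2 * spec$glc_rate,
                  EX_o2_e = 0)),
    hypoxia = list(
      objective = slp_total + atp_per_o2 * o2_fraction * spec$o2_rate,
      markers = c(GLYC = spec$glc_rate,
                  EX_o2_e = -o2_fraction * spec$o2_rate)),
    aerobic = list(
      objective = slp_total + atp_per_o2 * spec$o2_rate,
      markers = c(GLYC = spec$glc_rate, EX_o2_e = -spec$o2_rate))
  )
}

#' Parameters of the synthetic proteomics generator
#'
#' @param n_per_group samples per group (sham, injured); default 3.
#' @param planted named numeric vector of planted log2 fold changes
#'   (injured vs sham). The default plants a large positive glycogen
#'   phosphorylase effect (PYGB, log2FC 5.581) plus strong effects
#'   (|log2FC| 2.6-3.2, i.e. 6- to 9-fold) on the toy model's other
#'   flux-relevant enzymes, signed to match the direction of the
#'   corresponding flux shifts under oxygen/buffering stress. The
#'   magnitudes are deliberately large: with 3 samples per group, a
#'   log2-noise of 0.2 and 200 genes, the Benjamini-Hochberg criterion
#'   (q <= 0.05) requires roughly p < alpha * k / m = 0.0025, which a
#'   planted effect only clears reliably when |log2FC|/noise exceeds about
#'   12; smaller effects would make the planted set irrecoverable by design
#'   at this sample size.
#' @param n_genes total genes in the table (planted genes plus null
#'   background, default 200).
#' @param noise_sd log2-scale measurement noise standard deviation.
#' @param base_mean,base_sd log2-scale distribution of per-gene baseline
#'   abundance.
#' @param seed RNG seed for reproducible tables.
#' @export
proteomics_spec <- function(n_per_group = 3,
                            planted = c(PYGB = 5.581, PKM = 3.0,
                                        G6PD = 2.8, HEXA = 2.6,
                                        PDHA1 = -3.0, NDUFA11 = -3.2,
                                        COX4I1 = -2.8, SDHA = -2.6,
                                        CPT2 = -2.9, PGM2 = -3.1),
                            n_genes = 200, noise_sd = 0.2,
                            base_mean = 20, base_sd = 1.5, seed = 1L) {
  stopifnot(n_per_group >= 2, noise_sd > 0, n_genes >= length(planted))
  if (anyDuplicated(names(planted))) {
    stop("duplicate gene symbols in planted effect map", call. = FALSE)
  }
  structure(as.list(environment()), class = "proteomics_spec")
}

#' Generate a synthetic two-group proteomics experiment
#'
#' Emulates a normalized label-free LC-MS/MS comparison of `n_per_group`
#' sham vs injured samples: per-gene log-normal abundances with shared
#' log2-scale noise, and planted genes shifted by their log2 fold change in
#' the injured group. No missingness model.
#'
#' @param spec a [proteomics_spec()].
#' @return object of class `"proteomics_experiment"`: list with `abundance`
#'   (genes x samples matrix of positive linear-scale intensities), `genes`,
#'   `group` (factor sham/injured) and `planted`.
#' @export
generate_synthetic_proteomics <- function(spec = proteomics_spec()) {
  stopifnot(inherits(spec, "proteomics_spec"))
  n_bg <- spec$n_genes - length(spec$planted)
  genes <- c(names(spec$planted),
             sprintf("NULLP%03d", seq_len(n_bg)))
  set.seed(spec$seed)
  ns <- spec$n_per_group
  group <- factor(rep(c("sham", "injured"), each = ns),
                  levels = c("sham", "injured"))
  base <- stats::rnorm(length(genes), spec$base_mean, spec$base_sd)
  shift <- c(spec$planted, rep(0, n_bg))
  lmat <- matrix(base, nrow = length(genes), ncol = 2 * ns)
  lmat[, group == "injured"] <- lmat[, group == "injured"] + shift
  lmat <- lmat + matrix(stats::rnorm(length(lmat), 0, spec$noise_sd),
                        nrow = nrow(lmat))
  ab <- 2 ^ lmat
  dimnames(ab) <- list(genes, paste0(group, "_", rep(seq_len(ns), 2)))
  structure(list(abundance = ab, genes = genes, group = group,
                 planted = spec$planted),
            class = "proteomics_experiment")
}

#' @export
print.proteomics_experiment <- function(x, ...) {
  cat(sprintf("<proteomics_experiment> %d genes x %d samples (%d per group), %d planted effects\n",
              nrow(x$abundance), ncol(x$abundance),
              sum(x$group == levels(x$group)[1]), length(x$planted)))
  invisible(x)
}

#' Bundled astrocyte uptake/release rate table
#'
#' The physiological exchange-rate table shipped with the package
#' (µmol/g/min, one row per metabolite with a direction flag), as used to
#' constrain the steady-state condition.
#'
#' @return data.frame with columns `metabolite`, `rate`, `direction`.
#' @export
astrocyte_rate_table <- function() {
  path <- system.file("extdata", "astrocyte_rates.tsv", package = "astroflux",
                      mustWork = TRUE)
  read_rate_table(path)
}

#' Write the package's synthetic fixtures to a directory
#'
#' Writes the toy model (JSON), the astrocyte rate table (TSV) and a
#' synthetic differentially-expressed-protein table (TSV) so the full
#' pipeline can be exercised from files alone.
#'
#' @param dir output directory (created if needed).
#' @param seed seed for the proteomics table.
#' @return invisibly, the paths written.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(model = file.path(dir, "toy_model.json"),
             rates = file.path(dir, "astrocyte_rates.tsv"),
             deps = file.path(dir, "synthetic_deps.tsv"))
  write_model_json(generate_toy_astrocyte_model(), paths[["model"]])
  file.copy(system.file("extdata", "astrocyte_rates.tsv",
                        package = "astroflux", mustWork = TRUE),
            paths[["rates"]], overwrite = TRUE)
  expt <- generate_synthetic_proteomics(proteomics_spec(seed = seed))
  deps <- bh_fill(compute_differential(expt))
  utils::write.table(
    data.frame(gene = deps$gene, log2fc = deps$log2fc, pvalue = deps$pvalue,
               qvalue = deps$qvalue),
    paths[["deps"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
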