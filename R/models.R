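# Built-in models: the NF-kB core pathway (base), its modified-state variants
# (mNFkB, m2NFkB), the downstream EGR1/COX-2 gene module, and a small
# limit-cycle oscillator used as a desk-scale test fixture.
#
# The base model follows the published two-compartment NF-kB system of the
# Ashall-type family: an IKK neutral/active/inactive cycle driven by TNFa, the
# IkBa negative-feedback loop (NF-kB-driven transcription, translation,
# IKK-mediated IkBa degradation) and nucleocytoplasmic shuttling, rewritten
# with all concentrations expressed in a single volume Omega (units L/nM).
# Units are nM and minutes. The provenance tag of each constant records
# whether it is a published value of that model family converted to these
# units ("ref-model") or a nominal reconstruction ("reconstructed"); the
# supplementary source listing exact values was not available when this
# package was written, so reconstructed values were chosen once to reproduce
# the documented qualitative behaviour (sustained ~100 min nuclear NF-kB
# oscillations under continuous TNFa) and are not tuned thereafter.

mass_reaction <- function(name, rate, reactants = c(), products = c(),
                          factors = list()) {
  list(name = name, rate = rate, reactants = as.list(reactants),
       products = as.list(products), factors = factors)
}

hill_act <- function(source, K, h = 1, source2 = NULL)
  list(type = "hill_act", source = source, source2 = source2, K = K, h = h)
hill_rep <- function(source, K, h = 1, source2 = NULL)
  list(type = "hill_rep", source = source, source2 = source2, K = K, h = h)
power_fac <- function(source, n = 1) list(type = "power", source = source, n = n)

nfkb_params <- function() {
  c(TNFKB = 80,    # total NF-kB (nM)
    IKKTOT = 80,   # total IKK (nM)
    dose = 10,     # TNFa level (ng/ml-equivalent)
    kTNF = 0.1,    # dose half-saturation of IKK activation (ng/ml)
    ka = 0.24,     # IKKn -> IKKa, x dose factor (min^-1)
    ki = 0.18,     # IKKa -> IKKi (A20-independent part)
    kp = 0.036,    # IKKi -> IKKn recycling
    ka20 = 0.1,    # A20-catalysed IKKa -> IKKi (nM^-1 min^-1)
    ka1a = 0.03,   # IkBa + NF-kB association (nM^-1 min^-1), both compartments
    kd1a = 0.03,   # complex dissociation
    kc1a = 0.0045, # IKKa-catalysed degradation of complexed IkBa (nM^-1 min^-1)
    kc2a = 0.009,  # IKKa-catalysed degradation of free IkBa
    c5a = 0.03,    # constitutive free IkBa degradation
    c1a = 0.12,    # maximal IkBa transcription (nM/min)
    kNhill = 65,   # transcription Hill constant (nM), h = 2
    c3a = 0.024,   # mRNA degradation (IkBa and A20)
    c4a = 30,      # IkBa translation per transcript (min^-1)
    c4A = 0.5,     # A20 translation per transcript (min^-1)
    c5A = 0.03,    # A20 protein degradation
    ki1 = 2,       # NF-kB nuclear import
    ke1 = 0.003,   # NF-kB nuclear export
    ki3a = 0.04,   # IkBa nuclear import
    ke3a = 0.02,   # IkBa nuclear export
    ke2a = 0.6)    # nuclear complex export
}

nfkb_provenance <- function(extra = character()) {
  ref <- c("IKKTOT", "ka", "ki", "kp", "ka1a", "kd1a", "kc1a", "c3a", "c4a",
           "ke1", "ke2a", "kNhill", "TNFKB")
  p <- names(nfkb_params())
  out <- setNames(ifelse(p %in% ref, "ref-model", "reconstructed"), p)
  c(out, setNames(rep("reconstructed", length(extra)), extra))
}

# Reactions specific to one NF-kB pool, with species suffix `suf` ("" for the
# unmodified pool, "m" for the modified one). The two pools share the free
# IkBa species, which is what makes them compete for IkBa binding.
nfkb_pair_reactions <- function(suf = "") {
  N <- function(s) paste0(s, suf)
  list(
    mass_reaction(paste0("assoc_c", suf), "ka1a",
                  setNames(list(1, 1), c("IkBa_c", N("NFkB_c"))),
                  setNames(list(1), N("cplx_c"))),
    mass_reaction(paste0("dissoc_c", suf), "kd1a",
                  setNames(list(1), N("cplx_c")),
                  setNames(list(1, 1), c("IkBa_c", N("NFkB_c")))),
    mass_reaction(paste0("assoc_n", suf), "ka1a",
                  setNames(list(1, 1), c("IkBa_n", N("NFkB_n"))),
                  setNames(list(1), N("cplx_n"))),
    mass_reaction(paste0("dissoc_n", suf), "kd1a",
                  setNames(list(1), N("cplx_n")),
                  setNames(list(1, 1), c("IkBa_n", N("NFkB_n")))),
    mass_reaction(paste0("cplx_release", suf), "kc1a",
                  setNames(list(1), N("cplx_c")),
                  setNames(list(1), N("NFkB_c")),
                  list(power_fac("IKKa"))),
    mass_reaction(paste0("nfkb_in", suf), "ki1",
                  setNames(list(1), N("NFkB_c")),
                  setNames(list(1), N("NFkB_n"))),
    mass_reaction(paste0("nfkb_out", suf), "ke1",
                  setNames(list(1), N("NFkB_n")),
                  setNames(list(1), N("NFkB_c"))),
    mass_reaction(paste0("cplxn_out", suf), "ke2a",
                  setNames(list(1), N("cplx_n")),
                  setNames(list(1), N("cplx_c"))))
}

nfkb_shared_reactions <- function(tx_source, tx_source2 = NULL) {
  list(
    mass_reaction("txn_ikba", "c1a", c(), c(tIkBa = 1),
                  list(hill_act(tx_source, "kNhill", h = 2,
                                source2 = tx_source2))),
    mass_reaction("mrna_deg", "c3a", c(tIkBa = 1), c()),
    mass_reaction("translation", "c4a", c(), c(IkBa_c = 1),
                  list(power_fac("tIkBa"))),
    mass_reaction("ikba_deg_c", "c5a", c(IkBa_c = 1), c()),
    mass_reaction("ikba_ikk_deg", "kc2a", c(IkBa_c = 1), c(),
                  list(power_fac("IKKa"))),
    mass_reaction("ikba_in", "ki3a", c(IkBa_c = 1), c(IkBa_n = 1)),
    mass_reaction("ikba_out", "ke3a", c(IkBa_n = 1), c(IkBa_c = 1)),
    mass_reaction("txn_a20", "c1a", c(), c(tA20 = 1),
                  list(hill_act(tx_source, "kNhill", h = 2,
                                source2 = tx_source2))),
    mass_reaction("mrna_a20_deg", "c3a", c(tA20 = 1), c()),
    mass_reaction("transl_a20", "c4A", c(), c(A20 = 1),
                  list(power_fac("tA20"))),
    mass_reaction("a20_deg", "c5A", c(A20 = 1), c()),
    mass_reaction("ikk_act", "ka", c(IKKn = 1), c(IKKa = 1),
                  list(hill_act("dose", "kTNF", h = 1))),
    mass_reaction("ikk_inact", "ki", c(IKKa = 1), c(IKKi = 1)),
    mass_reaction("ikk_inact_a20", "ka20", c(IKKa = 1), c(IKKi = 1),
                  list(power_fac("A20"))),
    mass_reaction("ikk_recycle", "kp", c(IKKi = 1), c(IKKn = 1)))
}

build_nfkb_base <- function(omega = 100) {
  species <- c("IkBa_c", "NFkB_c", "cplx_c", "IkBa_n", "NFkB_n", "cplx_n",
               "tIkBa", "tA20", "A20", "IKKn", "IKKa", "IKKi")
  reactions <- c(nfkb_shared_reactions("NFkB_n"), nfkb_pair_reactions(""))
  reaction_network(species, reactions, nfkb_params(), omega,
                   variant = "base", dose_param = "dose",
                   init = list(cplx_c = "TNFKB", IKKn = "IKKTOT"),
                   provenance = nfkb_provenance())
}

build_nfkb_modified <- function(variant = c("mNFkB", "m2NFkB"),
                                omega = 100) {
  variant <- match.arg(variant)
  species <- c("IkBa_c", "NFkB_c", "cplx_c", "IkBa_n", "NFkB_n", "cplx_n",
               "NFkB_cm", "NFkB_nm", "cplx_cm", "cplx_nm",
               "tIkBa", "tA20", "A20", "IKKn", "IKKa", "IKKi")
  params <- c(nfkb_params(),
              p_m1 = 0.12, # maximal modification rate (min^-1)
              p_d1 = 0.03, # reverse modification rate (min^-1)
              S2 = 1,      # independent modification signal (a.u.)
              kS2 = 1,     # S2 half-saturation
              kIKKm = 5)   # IKKa half-saturation of modification (m2 only)
  mod_factors <- list(hill_act("S2", "kS2", h = 1))
  if (variant == "m2NFkB") # AND logic: requires both S2 and active IKK
    mod_factors <- c(mod_factors, list(hill_act("IKKa", "kIKKm", h = 1)))
  reactions <- c(
    nfkb_shared_reactions("NFkB_n", "NFkB_nm"),
    nfkb_pair_reactions(""), nfkb_pair_reactions("m"),
    list(
      mass_reaction("nfkb_mod", "p_m1", c(NFkB_c = 1), c(NFkB_cm = 1),
                    mod_factors),
      mass_reaction("nfkb_demod", "p_d1", c(NFkB_cm = 1), c(NFkB_c = 1))))
  reaction_network(species, reactions, params, omega,
                   variant = variant, dose_param = "dose",
                   init = list(cplx_c = "TNFKB", IKKn = "IKKTOT"),
                   provenance = nfkb_provenance(
                     c("p_m1", "p_d1", "S2", "kS2", "kIKKm")))
}

# Downstream gene module: EGR1 transcription activated by nuclear NF-kB and
# repressed by nuclear mNF-kB; the reverse regulation on COX-2. The nuclear
# transcription-factor species are drivers (zero stoichiometry rows) imposed
# from a core-model path during hybrid simulation. Constants are fixture
# values (non-paper), chosen for copy numbers of order tens.
build_gene_module <- function(omega = 100) {
  species <- c("EGR1", "COX2", "NFkB_n", "NFkB_nm")
  # kEGm is sized to the free nuclear modified pool (a few nM at most: the
  # bulk of modified NF-kB is sequestered by IkBa), so that mNF-kB actually
  # regulates the genes; kEG matches typical nuclear NF-kB peaks
  params <- c(k_egr = 0.03,  # maximal EGR1 transcription (nM/min)
              k_cox = 0.03,
              kEG = 30, kEGm = 2, # Hill constants (nM)
              d_egr = 0.03, d_cox = 0.02)
  reactions <- list(
    mass_reaction("egr_tx", "k_egr", c(), c(EGR1 = 1),
                  list(hill_act("NFkB_n", "kEG", h = 2),
                       hill_rep("NFkB_nm", "kEGm", h = 2))),
    mass_reaction("egr_deg", "d_egr", c(EGR1 = 1), c()),
    mass_reaction("cox_tx", "k_cox", c(), c(COX2 = 1),
                  list(hill_act("NFkB_nm", "kEGm", h = 2),
                       hill_rep("NFkB_n", "kEG", h = 2))),
    mass_reaction("cox_deg", "d_cox", c(COX2 = 1), c()))
  reaction_network(species, reactions, params, omega,
                   variant = "gene_module", dose_param = NA_character_,
                   provenance = setNames(rep("fixture", length(params)),
                                         names(params)))
}

# Two-species mass-action limit-cycle oscillator (Brusselator):
#   0 -> X (a); X -> Y (b); 2X + Y -> 3X (c); X -> 0 (d)
# with a limit cycle for b > 1 + a^2. b = 2.5 sits close enough to the Hopf
# point for a near-harmonic cycle (period ~ 6.6, X in [0.39, 2.6]), a regime
# where the LNA is accurate at omega = 1000 - the fixture validates the
# machinery, not LNA breakdown.
build_toy <- function(omega = 1000) {
  species <- c("X", "Y")
  params <- c(a = 1, b = 2.5, cc = 1, dd = 1)
  reactions <- list(
    mass_reaction("birth", "a", c(), c(X = 1)),
    mass_reaction("convert", "b", c(X = 1), c(Y = 1)),
    mass_reaction("autocat", "cc", c(X = 2, Y = 1), c(X = 3)),
    mass_reaction("death", "dd", c(X = 1), c()))
  reaction_network(species, reactions, params, omega,
                   variant = "toy", dose_param = NA_character_,
                   init = list(X = 1, Y = 1),
                   provenance = setNames(rep("fixture", 4), names(params)))
}

#' Build a packaged model variant
#'
#' Variants: `"base"` (NF-kB core pathway: IKK activation cycle, IkBa
#' negative-feedback loop, nucleocytoplasmic shuttling), `"mNFkB"` (adds a
#' reversibly modified cytoplasmic NF-kB state driven by an independent
#' signal `S2`, competing with the unmodified form for IkBa binding but
#' otherwise subject to the same reactions), `"m2NFkB"` (the modification
#' additionally requires active IKK: AND logic with the TNFa stimulus,
#' implemented as a product of saturating terms in `S2` and `IKKa`),
#' `"gene_module"` (downstream EGR1/COX-2 transcription driven by nuclear
#' NF-kB states), and `"toy"` (a two-species mass-action limit-cycle
#' oscillator used as a fast test fixture).
#'
#' @param variant model tag.
#' @param omega system size (L/nM); `NULL` uses each variant's default (100
#'   for the NF-kB models, matching copy numbers of a few thousand for
#'   nuclear NF-kB; 1000 for the toy oscillator).
#' @return a `ReactionNetwork`.
#' @export
build_model <- function(variant = c("base", "mNFkB", "m2NFkB",
                                    "gene_module", "toy"), omega = NULL) {
  if (!is.character(variant) || !variant[1] %in%
        c("base", "mNFkB", "m2NFkB", "gene_module", "toy"))
    stop("unknown variant '", variant[1],
         "'; valid tags: base, mNFkB, m2NFkB, gene_module, toy")
  variant <- match.arg(variant)
  if (is.null(omega)) omega <- if (variant == "toy") 1000 else 100
  switch(variant,
         base = build_nfkb_base(omega),
         mNFkB = build_nfkb_modified("mNFkB", omega),
         m2NFkB = build_nfkb_modified("m2NFkB", omega),
         gene_module = build_gene_module(omega),
         toy = build_toy(omega))
}
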