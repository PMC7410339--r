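# Documentation-grade region configuration for a genome-scale co-feeding
# strain design: growth-coupled 2,3-butanediol (2,3-BDO) production in an
# E. coli model (BiGG/iML1515 reaction ids), with glucose, acetate and
# glycerol as possible substrates.
#
# This file is a template, not a runnable fixture: the genome-scale model is
# not shipped with the package. To use it, (1) obtain iML1515 (SBML), extend
# it with the heterologous 2,3-BDO pathway (acetolactate synthase,
# acetolactate decarboxylase, butanediol dehydrogenase and an exchange
# EX_btd_RR_e), (2) mark EX_ac_e (uptake direction), EX_glyc_e and EX_glc__D_e
# as addable substrate supplies and gene pseudo-reactions as deletable, and
# (3) replace 0.164 below by 0.3 x the maximum stoichiometric carbon yield of
# 2,3-BDO on glucose computed for your model (by FBA).
#
# Substrate terms are weighted by carbon atoms (glucose 6, glycerol 3,
# acetate 2; 2,3-BDO has 4), so each yield row bounds the carbon recovery in
# the product. Exchange fluxes follow the model convention: positive =
# export, negative = import, hence the '+' signs on the uptake terms inside
# a row of the form  4 r_product + Y_c * (6 r_glc + ...) <= 0.
#
# Acetate is both a possible by-product and a possible co-substrate, so the
# low-yield states are covered by two target regions: one with acetate uptake
# pinned to zero, one with acetate export pinned to zero (the package's
# make_cofeeding_target_pair() builds the same structure programmatically).

- role: target
  label: low_yield_acetate_byproduct
  constraints:
    - "4 EX_btd_RR_e + 0.164 EX_glc__D_e + 0.082 EX_glyc_e <= 0"
    - "EX_glc__D_e <= -0.1"      # minimum substrate uptake excludes r = 0
    - "EX_ac_e >= 0"             # acetate not taken up in this region

- role: target
  label: low_yield_acetate_cosubstrate
  constraints:
    - "4 EX_btd_RR_e + 0.164 EX_glc__D_e + 0.0547 EX_ac_e + 0.082 EX_glyc_e <= 0"
    - "EX_glc__D_e <= -0.1"
    - "EX_ac_e <= 0"             # acetate not excreted in this region

- role: desired
  label: growth_per_carbon
  constraints:
    - "-1 BIOMASS_Ec_iML1515_core_75p37M - 0.005 EX_glc__D_e - 0.00166 EX_ac_e - 0.0025 EX_glyc_e <= 0"
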