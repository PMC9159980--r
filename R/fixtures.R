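#' African mole-rat study taxa, body masses and sample sizes
#'
#' Species-level summary of the eight bathyergid study species: taxon code,
#' full name, digging mode, mean adult body mass (grams, sexes averaged) and
#' skeletal sample size. Used to parameterize realistic body-mass ranges in
#' the synthetic generators.
#'
#' @return Tibble with columns `species` (two/three-letter code), `name`,
#'   `digging_mode`, `n`, `body_mass_g`.
#' @export
molerat_body_mass <- function() {
  tibble::tribble(
    ~species, ~name,                           ~digging_mode,   ~n, ~body_mass_g,
    "Bs", "Bathyergus suillus",                "scratch",       78L, 866.85,
    "Bj", "Bathyergus janetta",                "scratch",        6L, 384.5,
    "Ha", "Heliophobius argenteocinereus",     "chisel-tooth",  38L, 176,
    "Gc", "Georychus capensis",                "chisel-tooth",  51L, 180.5,
    "Ch", "Cryptomys hottentotus",             "chisel-tooth",  53L, 56.3,
    "Fm", "Fukomys mechowii",                  "chisel-tooth",  32L, 480.8,
    "Fd", "Fukomys damarensis",                "chisel-tooth",  48L, 140,
    "Hg", "Heterocephalus glaber",             "chisel-tooth",  76L, 33.9
  )
}

#' Observed presence/absence of bone superstructures across the study taxa
#'
#' Tip-state codings of four discrete limb-bone superstructures for the eight
#' bathyergid species and the three outgroups (Petromuridae, Thryonomyidae,
#' Hystricidae):
#'
#' * `DT` (projected deltoid tuberosity): present in all taxa except the naked
#'   mole-rat (Hg).
#' * `TT` (third trochanter): present in all eight bathyergids, absent in the
#'   three outgroups.
#' * `DFTFi` (distal tibio-fibular fusion): present in seven bathyergids,
#'   absent in Hg and the three outgroups.
#' * `OP` (olecranon process): present in every taxon — a constant character,
#'   included to exercise the constant-character guard.
#'
#' @return Tibble with columns `species`, `character`, `state`
#'   (`"present"`/`"absent"`).
#' @export
molerat_tip_states <- function() {
  bath <- c("Bs", "Bj", "Ch", "Fd", "Fm", "Gc", "Ha", "Hg")
  out <- c("Pt", "Ts", "Hya")
  all_taxa <- c(bath, out)
  states <- function(char, present) {
    tibble::tibble(
      species = all_taxa, character = char,
      state = ifelse(all_taxa %in% present, "present", "absent")
    )
  }
  dplyr::bind_rows(
    states("DT", setdiff(all_taxa, "Hg")),
    states("TT", bath),
    states("DFTFi", setdiff(bath, "Hg")),
    states("OP", all_taxa)
  )
}

#' Synthetic reference phylogeny of the study taxa
#'
#' A time-calibrated 11-taxon tree (8 bathyergids + Hystrix, Petromus,
#' Thryonomys) constructed in code as a stand-in for a published consensus
#' tree: the topology follows the accepted relationships of the group
#' (Heterocephalus basal within Bathyergidae, then Heliophobius, then
#' (Georychus, Bathyergus) and (Cryptomys, Fukomys)); the Heterocephalus
#' (29.02 Ma) and Heliophobius (13.37 Ma) divergence dates follow published
#' estimates, the remaining node ages are plausible round values. It is a
#' synthetic artifact, not a downloaded tree.
#'
#' @return Ultrametric `phylo` with 11 tips, height 44 Ma.
#' @export
molerat_reference_tree <- function() {
  parse_newick(paste0(
    "(Hya:44,((Pt:32,Ts:32):8,(Hg:29.02,(Ha:13.37,",
    "(((Bs:3,Bj:3):5,Gc:8):3,((Fd:4,Fm:4):6,Ch:10):1):2.37",
    "):15.65):10.98):4);"
  ))
}

#' Synthetic posterior-like sample of reference phylogenies
#'
#' Emulates a posterior sample of time-calibrated trees by jittering the node
#' ages of [molerat_reference_tree()]: each internal node age is multiplied by
#' independent lognormal noise and ages are re-monotonized along root-to-tip
#' paths so every tree stays ultrametric with positive branches. Topology is
#' held fixed. A stand-in for a downloaded posterior sample; only the spread
#' of node heights is emulated.
#'
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed.
#' @param age_cv Coefficient of variation of the lognormal age jitter
#'   (default 0.1).
#' @return `multiPhylo` of `n_trees` ultrametric trees on the 11 study taxa.
#' @export
molerat_reference_tree_sample <- function(n_trees = 100, seed = 1, age_cv = 0.1) {
  base <- molerat_reference_tree()
  ntip <- ape::Ntip(base)
  depths <- ape::node.depth.edgelength(base)
  h <- max(depths[seq_len(ntip)])
  age <- h - depths  # node ages above the tips
  sdlog <- sqrt(log(1 + age_cv^2))
  with_seed(seed, {
    trees <- vector("list", n_trees)
    for (t in seq_len(n_trees)) {
      tr <- base
      new_age <- age
      idx <- ntip + seq_len(base$Nnode)
      new_age[idx] <- age[idx] * exp(rnorm(length(idx), -sdlog^2 / 2, sdlog))
      # monotonize: a parent must be older than each child
      ord <- ape::reorder.phylo(base, "postorder")
      for (e in seq_len(nrow(ord$edge))) {
        par <- ord$edge[e, 1]
        chi <- ord$edge[e, 2]
        if (new_age[par] <= new_age[chi]) {
          new_age[par] <- new_age[chi] + 0.01 * h
        }
      }
      tr$edge.length <- new_age[tr$edge[, 1]] - new_age[tr$edge[, 2]]
      trees[[t]] <- tr
    }
    structure(trees, class = "multiPhylo", n_trees = n_trees)
  })
}

#' Simulate a full mole-rat-shaped measurement study
#'
#' Generates an individual-level bone-index dataset calibrated to the study
#' conditions: the eight bathyergid species with Table-style mean body masses,
#' per-species sample sizes chosen so the IFA dataset has 247 individuals and
#' the RDT/TJI datasets 151 after excluding the naked mole-rat (whose deltoid
#' tuberosity and tibio-fibular fusion are absent), weak allometric scaling,
#' and between-species variability dominated by the species-specific (rather
#' than phylogenetic) component.
#'
#' @param index One of `"IFA"`, `"RDT"`, `"TJI"`.
#' @param seed Integer seed.
#' @param tree Phylogeny of the 8 species; default: the bathyergid clade of
#'   [molerat_reference_tree()], unit height.
#' @param alpha_bar Grand intercept on the log-index scale; defaults to
#'   log(25) for IFA, log(50) for RDT/TJI (typical percent levels).
#' @param beta_bar Grand slope of log index on centered log body mass
#'   (default 0.1: weak positive scaling).
#' @param sigma_a_phy,sigma_a_sp,sigma_b_phy,sigma_b_sp Varying-effect scales
#'   (defaults 0.05, 0.2, 0.02, 0.05: species-specific dominates phylogenetic).
#' @param sigma Residual sd of log index (default 0.1).
#' @param bm_log_sd Within-species sd of log body mass (default 0.2).
#' @return Index-record tibble (see [simulate_measurements()]) with `truth`
#'   attribute; naked-mole-rat rows are flagged absent for RDT/TJI.
#' @export
simulate_molerat_study <- function(index = c("IFA", "RDT", "TJI"), seed = 1,
                                   tree = NULL,
                                   alpha_bar = NULL, beta_bar = 0.1,
                                   sigma_a_phy = 0.05, sigma_a_sp = 0.2,
                                   sigma_b_phy = 0.02, sigma_b_sp = 0.05,
                                   sigma = 0.1, bm_log_sd = 0.2) {
  index <- match.arg(index)
  if (is.null(tree)) {
    tree <- to_unit_height(ape::keep.tip(molerat_reference_tree(),
                                         molerat_body_mass()$species))
  }
  if (is.null(alpha_bar)) alpha_bar <- if (index == "IFA") log(25) else log(50)
  bm <- molerat_body_mass()
  bm <- bm[match(tree$tip.label, bm$species), ]
  # per-species counts: naked mole-rat 96 ulnae; the other seven species share
  # 151 individuals in proportion to their skeletal sample sizes
  n_ifa <- c(Bs = 38L, Bj = 3L, Ha = 19L, Gc = 25L, Ch = 26L, Fm = 16L,
             Fd = 24L, Hg = 96L)
  eff <- simulate_varying_effects(
    tree, alpha_bar, beta_bar, sigma_a_phy, sigma_a_sp, sigma_b_phy,
    sigma_b_sp, seed = spawn_seed(seed, "effects")
  )
  absent <- if (index %in% c("RDT", "TJI")) "Hg" else character()
  simulate_measurements(
    eff,
    n_per_species = n_ifa[tree$tip.label],
    bm_log_mean = log(bm$body_mass_g),
    bm_log_sd = bm_log_sd,
    sigma = sigma,
    seed = spawn_seed(seed, "measurements"),
    index = index,
    absent_species = absent
  )
}
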