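#' Configuration for the synthetic pangenome generator
#'
#' Defaults emulate the study conditions the package targets: 23 genomes in
#' three phenotype groups of 10 resistant / 3 nonpermissive / 10 permissive;
#' 346 clusters core to all genomes; 464 susceptible-exclusive, 51
#' resistant-exclusive, and 28 nonpermissive-exclusive planted clusters; and
#' enough noise clusters (presence probability `theta`) to land per-genome
#' repertoires in the ~1700-2800 band with ~12,400 clusters overall. A
#' fraction `multi_copy_prob` of core clusters receives a second gene copy in
#' one random genome, so the single-copy core is a strict subset of the core
#' (mirroring the study's 291-of-346 ratio).
#'
#' @param n_resistant,n_nonpermissive,n_permissive Group sizes.
#' @param n_core Clusters planted in every genome.
#' @param n_exclusive Named integer vector: planted group-exclusive cluster
#'   counts for `resistant`, `nonpermissive`, `permissive`, and the combined
#'   `susceptible` (permissive + nonpermissive) grouping.
#' @param n_noise Clusters present in each genome independently with
#'   probability `theta` (empty clusters are re-seeded into one genome).
#' @param theta Noise-cluster presence probability.
#' @param multi_copy_prob Probability a core cluster gets a duplicate copy.
#' @param annotation_rate Probability a noise cluster carries a function
#'   annotation (planted clusters always carry one function each).
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return Config list of class `pangenome_sim_config`.
#' @export
pangenome_sim_config <- function(n_resistant = 10, n_nonpermissive = 3,
                                 n_permissive = 10,
                                 n_core = 346,
                                 n_exclusive = c(resistant = 51,
                                                 nonpermissive = 28,
                                                 permissive = 0,
                                                 susceptible = 464),
                                 n_noise = 11483, theta = 0.15,
                                 multi_copy_prob = 0.16,
                                 annotation_rate = 0.9,
                                 seed = 1L) {
  full <- c(resistant = 0, nonpermissive = 0, permissive = 0, susceptible = 0)
  full[names(n_exclusive)] <- n_exclusive
  stopifnot(theta >= 0, theta <= 1, all(full >= 0), n_core >= 0,
            n_noise >= 0, n_resistant >= 0, n_nonpermissive >= 0,
            n_permissive >= 0)
  structure(list(n_resistant = n_resistant,
                 n_nonpermissive = n_nonpermissive,
                 n_permissive = n_permissive,
                 n_core = n_core, n_exclusive = full, n_noise = n_noise,
                 theta = theta, multi_copy_prob = multi_copy_prob,
                 annotation_rate = annotation_rate, seed = as.integer(seed)),
            class = "pangenome_sim_config")
}

sim_genome_names <- function(cfg) {
  pad <- function(prefix, n) {
    if (n == 0) return(character(0))
    sprintf("%s%02d", prefix, seq_len(n))
  }
  list(resistant = pad("R", cfg$n_resistant),
       nonpermissive = pad("NP", cfg$n_nonpermissive),
       permissive = pad("P", cfg$n_permissive))
}

#' Simulate a group-structured pangenome with planted exclusive clusters
#'
#' Planted clusters are present (count 1) in every genome of their target
#' grouping and absent elsewhere; noise clusters are present independently
#' with probability `theta`. Every planted cluster carries one function
#' (accession `FN-<cluster>`), so enrichment on the result has a known truth
#' table. Deterministic for a fixed config.
#'
#' @param cfg A [pangenome_sim_config()].
#' @return List with elements `matrix` (a [gene_cluster_matrix()]),
#'   `phenotypes` (a [phenotype_map()]), and `truth` (tibble of planted
#'   clusters: `gene_cluster_id`, `accession`, `target`).
#' @export
simulate_pangenome <- function(cfg = pangenome_sim_config()) {
  stopifnot(inherits(cfg, "pangenome_sim_config"))
  set.seed(cfg$seed)
  gn <- sim_genome_names(cfg)
  genomes <- unlist(gn, use.names = FALSE)
  n_genomes <- length(genomes)
  targets <- list(resistant = gn$resistant,
                  nonpermissive = gn$nonpermissive,
                  permissive = gn$permissive,
                  susceptible = c(gn$permissive, gn$nonpermissive))
  for (tg in names(cfg$n_exclusive)) {
    if (cfg$n_exclusive[[tg]] > 0 && length(targets[[tg]]) == 0) {
      abort(paste0("Planting requested for empty group: ", tg),
            class = "panphen_argument_error")
    }
  }

  blocks <- list()
  truth <- list()
  id <- function(prefix, n) sprintf("%s_%05d", prefix, seq_len(n))

  if (cfg$n_core > 0) {
    core_ids <- id("GC_CORE", cfg$n_core)
    m <- matrix(1L, n_genomes, cfg$n_core,
                dimnames = list(genomes, core_ids))
    dup <- runif(cfg$n_core) < cfg$multi_copy_prob
    if (any(dup)) {
      m[cbind(sample.int(n_genomes, sum(dup), replace = TRUE), which(dup))] <- 2L
    }
    blocks$core <- m
    truth$core <- tibble(gene_cluster_id = core_ids,
                         accession = paste0("FN-", core_ids),
                         target = "core")
  }
  for (tg in names(cfg$n_exclusive)) {
    n <- cfg$n_exclusive[[tg]]
    if (n == 0) next
    ids <- id(paste0("GC_", toupper(tg)), n)
    m <- matrix(0L, n_genomes, n, dimnames = list(genomes, ids))
    m[genomes %in% targets[[tg]], ] <- 1L
    blocks[[tg]] <- m
    truth[[tg]] <- tibble(gene_cluster_id = ids,
                          accession = paste0("FN-", ids),
                          target = tg)
  }
  if (cfg$n_noise > 0) {
    ids <- id("GC_NOISE", cfg$n_noise)
    m <- matrix(rbinom(n_genomes * cfg$n_noise, 1L, cfg$theta),
                n_genomes, cfg$n_noise, dimnames = list(genomes, ids))
    empty <- which(colSums(m) == 0)
    if (length(empty) > 0) {
      m[cbind(sample.int(n_genomes, length(empty), replace = TRUE), empty)] <- 1L
    }
    storage.mode(m) <- "integer"
    blocks$noise <- m
    keep <- runif(cfg$n_noise) < cfg$annotation_rate
    truth$noise <- tibble(gene_cluster_id = ids[keep],
                          accession = paste0("FN-", ids[keep]),
                          target = "noise")
  }
  counts <- do.call(cbind, unname(blocks))
  # same deterministic lexicographic ordering the table loader uses
  counts <- counts[order(rownames(counts)), order(colnames(counts)),
                   drop = FALSE]
  truth <- dplyr::bind_rows(truth)
  functions <- tibble(gene_cluster_id = truth$gene_cluster_id,
                      accession = truth$accession,
                      annotation = paste0("synthetic function ",
                                          truth$accession))
  ph <- phenotype_map(tibble(
    genome_name = genomes,
    group = rep(c("resistant", "nonpermissive", "permissive"),
                times = c(cfg$n_resistant, cfg$n_nonpermissive,
                          cfg$n_permissive))))
  list(matrix = gene_cluster_matrix(counts, functions),
       phenotypes = ph,
       truth = dplyr::filter(truth, .data$target != "core"))
}

#' Configuration for the synthetic gene-tree generator
#'
#' @param genomes Named list of leaf names per group (default: the 10/3/10
#'   genomes of [pangenome_sim_config()]). Groups with zero leaves are
#'   dropped; with only permissive and nonpermissive leaves the concordant
#'   shape is the two-clade permissive/nonpermissive split.
#' @param n_trees Number of trees.
#' @param concordant_fraction Fraction of trees built concordant with the
#'   grouping (within-group clades, resistant sister to nonpermissive);
#'   the rest are random joins of all leaves.
#' @param polytomy_prob Probability each internal edge is contracted into a
#'   polytomy.
#' @param bl_rate Rate of the exponential branch-length distribution.
#' @param seed Integer seed.
#' @return Config list of class `tree_sim_config`.
#' @export
tree_sim_config <- function(genomes = sim_genome_names(pangenome_sim_config()),
                            n_trees = 200, concordant_fraction = 0.5,
                            polytomy_prob = 0, bl_rate = 10, seed = 1L) {
  stopifnot(concordant_fraction >= 0, concordant_fraction <= 1,
            polytomy_prob >= 0, polytomy_prob <= 1, n_trees >= 0)
  genomes <- genomes[lengths(genomes) > 0]
  structure(list(genomes = genomes, n_trees = n_trees,
                 concordant_fraction = concordant_fraction,
                 polytomy_prob = polytomy_prob, bl_rate = bl_rate,
                 seed = as.integer(seed)),
            class = "tree_sim_config")
}

# random rooted binary newick over tips by sequential random joining
random_join_newick <- function(tips, bl_rate) {
  nodes <- as.list(sample(tips))
  while (length(nodes) > 1) {
    i <- sample.int(length(nodes), 2)
    merged <- sprintf("(%s:%.6f,%s:%.6f)", nodes[[i[1]]], rexp(1, bl_rate),
                      nodes[[i[2]]], rexp(1, bl_rate))
    nodes <- c(nodes[-i], merged)
  }
  nodes[[1]]
}

collapse_edges <- function(tree, polytomy_prob) {
  if (polytomy_prob == 0) return(tree)
  internal <- which(tree$edge[, 2] > length(tree$tip.label))
  hit <- internal[runif(length(internal)) < polytomy_prob]
  if (length(hit) > 0) {
    tree$edge.length[hit] <- 0
    tree <- ape::di2multi(tree, tol = 1e-12)
  }
  tree
}

#' Simulate gene trees concordant or discordant with the phenotype grouping
#'
#' Concordant trees join within-group clades under the resistant-sister-to-
#' nonpermissive nesting (or the plain permissive/nonpermissive split for
#' two-group leaf sets); discordant trees join all leaves in random order.
#' Polytomies are introduced by contracting random internal edges.
#'
#' @param cfg A [tree_sim_config()].
#' @return List with `trees` (list of [parse_labeled_tree()] objects, cluster
#'   ids `GT_...`) and `truth` (tibble `cluster_id`, `concordant`).
#' @export
simulate_gene_trees <- function(cfg = tree_sim_config()) {
  stopifnot(inherits(cfg, "tree_sim_config"))
  set.seed(cfg$seed)
  groups <- cfg$genomes
  ph <- phenotype_map(tibble(
    genome_name = unlist(groups, use.names = FALSE),
    group = rep(names(groups), times = lengths(groups))))
  all_tips <- unlist(groups, use.names = FALSE)
  concordant <- runif(cfg$n_trees) < cfg$concordant_fraction
  sub <- function(tips) {
    if (length(tips) == 1) return(tips)
    random_join_newick(tips, cfg$bl_rate)
  }
  trees <- vector("list", cfg$n_trees)
  for (i in seq_len(cfg$n_trees)) {
    nwk <- if (concordant[i]) {
      bl <- function() sprintf("%.6f", rexp(1, cfg$bl_rate))
      if (!is.null(groups$resistant)) {
        sprintf("((%s:%s,%s:%s):%s,%s:%s);",
                sub(groups$resistant), bl(),
                sub(groups$nonpermissive), bl(), bl(),
                sub(groups$permissive), bl())
      } else {
        sprintf("(%s:%s,%s:%s);",
                sub(groups$permissive), bl(),
                sub(groups$nonpermissive), bl())
      }
    } else {
      paste0(random_join_newick(all_tips, cfg$bl_rate), ";")
    }
    tree <- collapse_edges(ape::read.tree(text = nwk), cfg$polytomy_prob)
    trees[[i]] <- parse_labeled_tree(tree, ph,
                                     cluster_id = sprintf("GT_%04d", i))
  }
  list(trees = trees,
       truth = tibble(cluster_id = sprintf("GT_%04d", seq_len(cfg$n_trees)),
                      concordant = concordant),
       phenotypes = ph)
}

#' Configuration for the serial-passage dynamics simulator
#'
#' A minimal discrete-passage consumer-resource sketch of epibiont/host
#' coculture: naive and resistant-variant host subpopulations grow
#' logistically within each 24 h passage; the parasite load grows in
#' proportion to load x naive hosts (attachment x replication, saturating at
#' a carrying cap); naive hosts die in proportion to the per-host load;
#' variants emerge from naive hosts at a small rate and are immune, driving
#' the recovery; every passage ends with a 1:10 dilution into fresh medium.
#' It reproduces the qualitative growth/crash/recovery pattern with a
#' dose-shifted crash point and makes no claim of mechanistic accuracy.
#'
#' `phenotype` presets: resistant hosts have `alpha = 0` (no attachment, the
#' parasite washes out), nonpermissive hosts have `delta = 0` (carriage
#' without damage), permissive hosts have both positive.
#'
#' @param phenotype One of `"resistant"`, `"permissive"`, `"nonpermissive"`.
#' @param dose Initial parasite-to-host cell ratio (>= 0).
#' @param n_passages Passages simulated after inoculation (indices 0..n).
#' @param growth_rate Host logistic growth rate per passage.
#' @param capacity Host carrying capacity (density units).
#' @param alpha Attachment coefficient (0 for resistant).
#' @param replication_rate Parasite replication rate per attached load.
#' @param delta Damage coefficient: naive-host death per unit per-host load
#'   (0 for nonpermissive).
#' @param epsilon Resistant-variant emergence rate from naive hosts.
#' @param variant_carriage Relative ability of variant hosts to carry and
#'   propagate the parasite (damage-free), sustaining the load after
#'   recovery.
#' @param dilution Fraction carried into the next passage (default 1/10).
#' @param parasite_cap Saturation cap on parasite load.
#' @param score_half Load at which the 0-1 parasite score reaches one half.
#' @param noise_sd Lognormal sd of density measurement noise (shared between
#'   coculture and control so dose-0 runs track the control exactly).
#' @param cfu_scale Colony-forming units per density unit.
#' @param steps_per_passage Integration substeps per passage.
#' @param strain Strain label carried into the output.
#' @param seed Integer seed.
#' @return Config list of class `passage_sim_config`.
#' @export
passage_sim_config <- function(phenotype = c("permissive", "nonpermissive",
                                             "resistant"),
                               dose = 3, n_passages = 12,
                               growth_rate = 6, capacity = 1,
                               alpha = NULL, replication_rate = 8,
                               delta = NULL, epsilon = 1e-4,
                               variant_carriage = 0.6,
                               dilution = 0.1, parasite_cap = 50,
                               score_half = 0.2, noise_sd = 0.02,
                               cfu_scale = 1e8, steps_per_passage = 60,
                               strain = NULL, seed = 1L) {
  phenotype <- match.arg(phenotype)
  alpha <- alpha %||% if (phenotype == "resistant") 0 else 1
  delta <- delta %||% if (phenotype == "nonpermissive") 0 else 15
  stopifnot(dose >= 0, alpha >= 0, delta >= 0, epsilon >= 0,
            replication_rate >= 0, growth_rate > 0, capacity > 0,
            dilution > 0, dilution < 1, n_passages >= 1)
  structure(list(phenotype = phenotype, dose = dose,
                 n_passages = as.integer(n_passages),
                 growth_rate = growth_rate, capacity = capacity,
                 alpha = alpha, replication_rate = replication_rate,
                 delta = delta, epsilon = epsilon,
                 variant_carriage = variant_carriage, dilution = dilution,
                 parasite_cap = parasite_cap, score_half = score_half,
                 noise_sd = noise_sd, cfu_scale = cfu_scale,
                 steps_per_passage = as.integer(steps_per_passage),
                 strain = strain %||% paste0("SIM_", phenotype),
                 seed = as.integer(seed)),
            class = "passage_sim_config")
}

# integrate one passage of within-culture dynamics (exponential Euler keeps
# all state positive)
passage_step <- function(state, cfg) {
  dt <- 1 / cfg$steps_per_passage
  r <- cfg$growth_rate; K <- cfg$capacity
  for (s in seq_len(cfg$steps_per_passage)) {
    htot <- state$hn + state$hv
    logis <- r * (1 - htot / K)
    load <- if (htot > 0) state$p / htot else 0
    hn_new <- state$hn * exp((logis - cfg$delta * load - cfg$epsilon) * dt)
    hv_new <- state$hv * exp(logis * dt) + cfg$epsilon * state$hn * dt
    hosts <- state$hn + cfg$variant_carriage * state$hv
    p_new <- state$p * exp(cfg$replication_rate * cfg$alpha * hosts *
                             (1 - state$p / cfg$parasite_cap) * dt)
    state <- list(hn = hn_new, hv = hv_new, p = p_new)
  }
  state
}

#' Simulate a serial-passage infection trajectory
#'
#' Runs the coculture and the host-alone control side by side and returns
#' both as a single passage table (control rows have `dose = 0`). Passage 0
#' records the inoculated state; each later passage records the culture at
#' the end of 24 h growth, before the 1:10 dilution. Deterministic for a
#' fixed config.
#'
#' @param cfg A [passage_sim_config()].
#' @return Tibble with columns `strain`, `dose`, `passage`, `density`,
#'   `parasite_score`, `total_cfu`, `irregular_cfu`.
#' @export
simulate_passages <- function(cfg = passage_sim_config()) {
  stopifnot(inherits(cfg, "passage_sim_config"))
  set.seed(cfg$seed)
  h0 <- 0.1 * cfg$capacity
  eta <- exp(stats::rnorm(cfg$n_passages + 1, 0, cfg$noise_sd))
  cc <- list(hn = h0, hv = 0, p = cfg$dose * h0)   # coculture
  ct <- list(hn = h0, hv = 0, p = 0)               # host-alone control
  score <- function(p) p / (p + cfg$score_half)
  rows <- vector("list", 2 * (cfg$n_passages + 1))
  emit <- function(state, dose, passage) {
    htot <- state$hn + state$hv
    tibble(strain = cfg$strain, dose = dose, passage = passage,
           density = htot * eta[passage + 1],
           parasite_score = round(min(1, score(state$p)), 6),
           total_cfu = round(htot * cfg$cfu_scale),
           irregular_cfu = round(min(state$p, state$hn) * cfg$cfu_scale))
  }
  rows[[1]] <- emit(cc, cfg$dose, 0L)
  rows[[2]] <- emit(ct, 0, 0L)
  for (p in seq_len(cfg$n_passages)) {
    cc <- passage_step(cc, cfg)
    ct <- passage_step(ct, cfg)
    if (!all(is.finite(unlist(cc))) || !all(is.finite(unlist(ct)))) {
      abort(paste0("Non-finite simulator state at passage ", p),
            class = "panphen_numeric_error")
    }
    rows[[2 * p + 1]] <- emit(cc, cfg$dose, p)
    rows[[2 * p + 2]] <- emit(ct, 0, p)
    dil <- function(s) list(hn = s$hn * cfg$dilution,
                            hv = s$hv * cfg$dilution,
                            p = s$p * cfg$dilution)
    cc <- dil(cc); ct <- dil(ct)
  }
  out <- dplyr::bind_rows(rows)
  if (cfg$dose == 0) out <- dplyr::distinct(out)
  dplyr::arrange(out, dplyr::desc(.data$dose), .data$passage)
}
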