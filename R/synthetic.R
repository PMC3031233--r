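# Constructive synthetic cohort generator. Labels are assigned first and
# every attribute is drawn conditional on the label, so the planted
# patterns' coverage counts are exact by construction (no rejection
# sampling) and can be asserted exactly downstream.

# DNA repair pathway vocabulary (12 nominal categories).
REPAIR_PATHWAYS <- c(
  "base_excision_repair", "mismatch_repair", "nucleotide_excision_repair",
  "homologous_recombination", "non_homologous_end_joining",
  "other_dna_repair", "dna_polymerases_catalytic_subunits",
  "editing_and_processing_nucleases", "rad6_pathway", "disease",
  "other_known_or_suspected_dna_repair",
  "other_conserved_dna_damage_response")

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of the real cohort: 140 DNA
#' repair genes of which 33 are ageing-related (class frequency 0.236), a
#' biological-process ontology whose closed annotations give a sparse
#' binary matrix, a PPI network in which positives have markedly more
#' partners (crossing 15) and a hub gene whose 11 cohort partners are 10
#' positives and 1 negative, a 108-tissue expression table with one tissue
#' (T lymphocytes) upshifted in positives, and a deliberately
#' non-predictive evolutionary-rate column.
#'
#' @param n_genes,n_positive Cohort size and number of ageing-related
#'   genes.
#' @param n_terms,max_depth,branching Ontology shape: number of
#'   biological-process terms, depth cap, and a weight base favouring
#'   deeper parents (larger values give deeper hierarchies).
#' @param mean_specific Mean number of specific GO annotations per gene.
#' @param n_planted_go,planted_go_pos,planted_go_neg Number of planted
#'   predictive GO terms and their annotation probabilities in the
#'   positive / negative class.
#' @param neg_partner_lambda Poisson mean of negative genes' partner
#'   counts (mode about 5).
#' @param pos_partner_min,pos_partner_lambda Positive genes' partner count
#'   is `pos_partner_min + Poisson(pos_partner_lambda)`; defaults put most
#'   positives above 15 partners.
#' @param hub_n_partners,hub_positive_partners The hub gene's number of
#'   cohort interaction partners and how many of them are positive
#'   (default 11 and 10).
#' @param hub_background_partners Extra background-protein partners wired
#'   to the hub so it ranks first among frequent interactors.
#' @param n_background Size of the background (non-cohort) protein pool.
#' @param n_decoy_ht,n_decoy_bg Decoy edges: cohort edges whose only
#'   evidence is high-throughput, and background-background edges; both
#'   are removed by interaction filtering.
#' @param n_tissues,planted_tissue,expression_shift Number of anatomy
#'   categories, the name of the planted tissue, and the multiplicative
#'   expression shift of positives in that tissue (1 = null, no signal).
#' @param expr_meanlog,expr_sdlog,probe_sdlog Lognormal location/scale of
#'   baseline expression (raw scale, medians in the low thousands) and
#'   probe-level noise.
#' @param probes_lambda Number of probes per gene is
#'   `1 + Poisson(probes_lambda)`.
#' @param expr_missing_rate Probability that a gene has no probe in a
#'   given anatomy category (missing cell).
#' @param kaki_meanlog,kaki_sdlog,kaki_missing_rate Lognormal parameters
#'   of the Ka/Ki column, identical in both classes (non-predictive), and
#'   its missingness rate.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 140, n_positive = 33,
                             n_terms = 150, max_depth = 8, branching = 3,
                             mean_specific = 4,
                             n_planted_go = 2, planted_go_pos = 0.6,
                             planted_go_neg = 0.08,
                             neg_partner_lambda = 5,
                             pos_partner_min = 8, pos_partner_lambda = 10,
                             hub_n_partners = 11, hub_positive_partners = 10,
                             hub_background_partners = 45,
                             n_background = 400,
                             n_decoy_ht = 40, n_decoy_bg = 30,
                             n_tissues = 108,
                             planted_tissue = "T_lymphocyte",
                             expression_shift = 3,
                             expr_meanlog = log(2000), expr_sdlog = 0.5,
                             probe_sdlog = 0.4, probes_lambda = 1,
                             expr_missing_rate = 0.02,
                             kaki_meanlog = log(0.25), kaki_sdlog = 0.4,
                             kaki_missing_rate = 0.15) {
  cfg <- as.list(environment())
  if (cfg$n_positive >= cfg$n_genes) abort("n_positive must be < n_genes")
  if (cfg$hub_n_partners > cfg$n_genes - 1) {
    abort("hub cannot have more cohort partners than there are other genes")
  }
  if (cfg$hub_positive_partners > cfg$hub_n_partners ||
      cfg$hub_positive_partners > cfg$n_positive - 1) {
    abort("infeasible hub partner composition")
  }
  probs <- c(cfg$planted_go_pos, cfg$planted_go_neg, cfg$expr_missing_rate,
             cfg$kaki_missing_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (cfg$n_terms < 3) abort("n_terms must be >= 3")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic biological-process ontology
#'
#' Builds a rooted DAG of `n_terms` terms, all in the
#' `biological_process` namespace, by attaching each new term to one (or
#' occasionally two) existing terms of depth below `max_depth`; parents
#' are sampled with weight `branching^depth`, which pushes the hierarchy
#' towards its depth cap. A small `molecular_function` branch (about 10%
#' of terms) is added so that namespace filtering is exercised
#' downstream. Deterministic given `seed`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return An [ontology] with a `depth` column on its term table.
#' @export
generate_ontology <- function(config = synthetic_config(), seed = 1) {
  n_bp <- config$n_terms
  n_mf <- max(3L, round(0.1 * n_bp))
  withr::with_seed(seed, {
    ids <- sprintf("GO:%07d", seq_len(n_bp + n_mf))
    depth <- integer(n_bp + n_mf)
    child <- character(0); parent <- character(0)
    two_parent_p <- 0.2
    # biological-process branch rooted at term 1
    for (i in 2:n_bp) {
      cand <- which(depth[seq_len(i - 1)] < config$max_depth)
      w <- config$branching^depth[cand]
      np <- if (length(cand) > 1 && runif(1) < two_parent_p) 2L else 1L
      par <- cand[sample.int(length(cand), min(np, length(cand)),
                             prob = w)]
      depth[i] <- max(depth[par]) + 1L
      child <- c(child, rep(ids[i], length(par)))
      parent <- c(parent, ids[par])
    }
    # molecular-function branch rooted at term n_bp + 1
    for (i in (n_bp + 2):(n_bp + n_mf)) {
      cand <- (n_bp + 1):(i - 1)
      par <- cand[sample.int(length(cand), 1)]
      depth[i] <- depth[par] + 1L
      child <- c(child, ids[i])
      parent <- c(parent, ids[par])
    }
    ns <- c(rep("biological_process", n_bp),
            rep("molecular_function", n_mf))
    terms <- tibble::tibble(
      id = ids,
      name = paste0(ifelse(ns == "biological_process", "process ",
                           "function "), seq_along(ids)),
      namespace = ns, depth = depth)
    ontology(terms, tibble::tibble(child = child, parent = parent))
  })
}

sample_evidence <- function(n) {
  pool <- list(c("in_vivo"), c("in_vitro"), c("in_vivo", "in_vitro"),
               c("in_vivo", "yeast_two_hybrid"),
               c("in_vitro", "high_throughput"))
  pool[sample.int(length(pool), n, replace = TRUE,
                  prob = c(0.35, 0.3, 0.2, 0.1, 0.05))]
}

#' Generate a complete synthetic cohort
#'
#' Emits gene records, specific GO annotations, a PPI edge list, a
#' probe-level expression table and the generating ontology, together
#' with a ground-truth record of every planted pattern. Generation is
#' constructive: exactly `n_positive` genes are positive, the hub gene
#' (`HUB1`, itself a positive cohort gene) is wired to exactly
#' `hub_n_partners` cohort partners of which `hub_positive_partners` are
#' positive, and the planted tissue's positive-class expression is drawn
#' from the shifted distribution. Fully deterministic given `seed`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A list of class `repair_cohort` with elements `genes`,
#'   `annotations`, `interactions`, `probes`, `ontology`, `truth`,
#'   `config`, `seed`.
#' @export
generate_cohort <- function(config = synthetic_config(), seed = 1) {
  graph <- generate_ontology(config, seed)
  withr::with_seed(seed + 1L, {
    n <- config$n_genes
    genes <- sprintf("RG%03d", seq_len(n))
    cls <- rep(c("ageing", "non_ageing"),
               c(config$n_positive, n - config$n_positive))
    # the hub is a positive cohort gene with a recognisable symbol
    genes[1] <- "HUB1"
    pathway <- sample(REPAIR_PATHWAYS, n, replace = TRUE,
                      prob = c(rep(2, 5), rep(1, 7)))
    ka_ki <- rlnorm(n, config$kaki_meanlog, config$kaki_sdlog)
    ka_ki[runif(n) < config$kaki_missing_rate] <- NA_real_
    gene_tbl <- tibble::tibble(gene = genes, class = cls,
                               pathway = pathway, ka_ki = ka_ki)

    # --- GO annotations -------------------------------------------------
    bp <- graph$terms[graph$terms$namespace == "biological_process", ]
    # plant on leaf terms (no descendants), so a planted column's yes-set
    # is exactly the directly annotated genes rather than a closure union
    leaves <- setdiff(bp$id, graph$edges$parent)
    planted_pool <- intersect(leaves, bp$id[bp$depth >= 3])
    planted_go <- sample(planted_pool,
                         min(config$n_planted_go, length(planted_pool)))
    deep <- setdiff(bp$id[bp$depth >= 2], planted_go)
    mf <- graph$terms$id[graph$terms$namespace == "molecular_function"]
    ann_gene <- character(0); ann_term <- character(0)
    for (i in seq_len(n)) {
      k <- 1L + rpois(1, max(config$mean_specific - 1, 0))
      terms_i <- sample(deep, min(k, length(deep)))
      p_pl <- if (cls[i] == "ageing") config$planted_go_pos else
        config$planted_go_neg
      terms_i <- union(terms_i, planted_go[runif(length(planted_go)) < p_pl])
      if (runif(1) < 0.2) terms_i <- c(terms_i, sample(mf, 1))
      ann_gene <- c(ann_gene, rep(genes[i], length(terms_i)))
      ann_term <- c(ann_term, terms_i)
    }
    annotations <- tibble::tibble(gene = ann_gene, go_id = ann_term)

    # --- PPI network ----------------------------------------------------
    background <- sprintf("BGP%03d", seq_len(config$n_background))
    pos_idx <- which(cls == "ageing")
    hub_pos <- sample(setdiff(pos_idx, 1L), config$hub_positive_partners)
    hub_neg <- sample(which(cls == "non_ageing"),
                      config$hub_n_partners - config$hub_positive_partners)
    hub_partners <- genes[sort(c(hub_pos, hub_neg))]
    ea <- character(0); eb <- character(0); ev <- list()
    add_edges <- function(a, b, evidence) {
      ea <<- c(ea, a); eb <<- c(eb, b); ev <<- c(ev, evidence)
    }
    # each gene's background partners (distinct proteins, no repeats)
    n_bg_partners <- integer(n)
    for (i in seq_len(n)) {
      n_bg_partners[i] <- if (i == 1L) {
        config$hub_background_partners
      } else if (cls[i] == "ageing") {
        config$pos_partner_min + rpois(1, config$pos_partner_lambda)
      } else {
        rpois(1, config$neg_partner_lambda)
      }
      if (n_bg_partners[i] > 0) {
        bg <- sample(background, n_bg_partners[i])
        add_edges(rep(genes[i], length(bg)), bg,
                  sample_evidence(length(bg)))
      }
    }
    add_edges(hub_partners, rep("HUB1", length(hub_partners)),
              sample_evidence(length(hub_partners)))
    # decoy edges removed by filtering: high-throughput-only evidence ...
    for (j in seq_len(config$n_decoy_ht)) {
      gi <- sample.int(n, 1)
      used <- unique(c(eb[ea == genes[gi]], ea[eb == genes[gi]]))
      free <- setdiff(background, used)
      add_edges(genes[gi], sample(free, 1), list("high_throughput"))
    }
    # ... and edges with no cohort endpoint
    bg_pairs <- matrix(sample(background, 2 * config$n_decoy_bg), ncol = 2)
    add_edges(bg_pairs[, 1], bg_pairs[, 2],
              sample_evidence(config$n_decoy_bg))
    interactions <- tibble::tibble(protein_a = ea, protein_b = eb,
                                   evidence = ev)

    # true filtered partner count per gene
    true_partners <- n_bg_partners
    true_partners[1] <- true_partners[1] + length(hub_partners)
    true_partners[genes %in% hub_partners] <-
      true_partners[genes %in% hub_partners] + 1L

    # --- expression -----------------------------------------------------
    tissues <- c(config$planted_tissue,
                 sprintf("tissue_%03d", seq_len(config$n_tissues - 1)))
    n_probes <- 1L + rpois(n, config$probes_lambda)
    cells <- tidyr::expand_grid(gi = seq_len(n), tissue = tissues)
    base_meanlog <- config$expr_meanlog +
      stats::rnorm(nrow(cells), 0, config$expr_sdlog)
    planted <- cells$tissue == config$planted_tissue &
      cls[cells$gi] == "ageing"
    base_meanlog[planted] <- base_meanlog[planted] +
      log(config$expression_shift)
    keep <- runif(nrow(cells)) >= config$expr_missing_rate
    cells <- cells[keep, ]
    base_meanlog <- base_meanlog[keep]
    reps <- n_probes[cells$gi]
    probes <- tibble::tibble(
      gene = rep(genes[cells$gi], reps),
      probe = paste0(rep(genes[cells$gi], reps), "_p",
                     sequence(reps)),
      anatomy_category = rep(cells$tissue, reps),
      value = rlnorm(sum(reps), rep(base_meanlog, reps),
                     config$probe_sdlog))

    truth <- list(
      hub = list(protein = "HUB1", partners = hub_partners,
                 n_partners = length(hub_partners),
                 n_positive = sum(hub_partners %in% genes[pos_idx]),
                 expected_coverage = c(n_trials = length(hub_partners),
                                       n_successes = sum(
                                         hub_partners %in% genes[pos_idx]))),
      planted_go = tibble::tibble(term = planted_go,
                                  pos_rate = config$planted_go_pos,
                                  neg_rate = config$planted_go_neg),
      planted_tissue = list(name = config$planted_tissue,
                            shift = config$expression_shift),
      partner_counts = tibble::tibble(gene = genes,
                                      n_partners = true_partners),
      partner_separation = 15,
      planted_attributes = c("n_partners", "HUB1_interaction",
                             planted_go)
    )
    structure(
      list(genes = gene_tbl, annotations = annotations,
           interactions = interactions, probes = probes, ontology = graph,
           truth = truth, config = config, seed = seed),
      class = "repair_cohort")
  })
}

#' @export
print.repair_cohort <- function(x, ...) {
  cat("<repair_cohort> seed", x$seed, "\n")
  cat("  genes:", nrow(x$genes), "(",
      sum(x$genes$class == "ageing"), "ageing )\n")
  cat("  annotations:", nrow(x$annotations),
      "| interactions:", nrow(x$interactions),
      "| probe rows:", nrow(x$probes), "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the formats the package's readers consume: an OBO
#' ontology, TSV tables for genes, annotations, interactions and probes,
#' and a ground-truth JSON. Same cohort, same bytes.
#'
#' @param cohort A `repair_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "repair_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ontology = file.path(dir, "ontology.obo"),
             genes = file.path(dir, "genes.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             ppi = file.path(dir, "ppi.tsv"),
             probes = file.path(dir, "probes.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_obo(cohort$ontology, paths[["ontology"]])
  write_tsv_plain <- function(df, path) {
    cols <- lapply(df, function(x) {
      if (is.numeric(x)) {
        out <- sprintf("%.17g", x); out[is.na(x)] <- "?"
      } else {
        out <- as.character(x); out[is.na(out)] <- "?"
      }
      out
    })
    writeLines(c(paste(names(df), collapse = "\t"),
                 do.call(paste, c(cols, sep = "\t"))), path)
  }
  write_tsv_plain(cohort$genes, paths[["genes"]])
  write_tsv_plain(cohort$annotations, paths[["annotations"]])
  ppi <- cohort$interactions
  ppi$evidence <- vapply(ppi$evidence, paste, character(1), collapse = ",")
  write_tsv_plain(ppi, paths[["ppi"]])
  write_tsv_plain(cohort$probes, paths[["probes"]])
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = I(17), dataframe = "columns")
  invisible(paths)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir Directory holding the cohort files.
#' @return A list with elements `genes`, `annotations`, `interactions`,
#'   `probes`, `ontology` (no ground truth is required to be present).
#' @export
read_cohort <- function(dir) {
  list(
    genes = read_gene_table(file.path(dir, "genes.tsv")),
    annotations = read_annotation_table(file.path(dir, "annotations.tsv")),
    interactions = read_ppi_table(file.path(dir, "ppi.tsv")),
    probes = read_probe_table(file.path(dir, "probes.tsv")),
    ontology = read_obo(file.path(dir, "ontology.obo"))
  )
}
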