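ppi_fixture <- function() {
  tibble::tibble(
    protein_a = c("X", "X", "P", "P", "Q"),
    protein_b = c("Y", "Y", "A", "B", "Q"),
    evidence = list("high_throughput", c("in_vitro", "yeast_two_hybrid"),
                    "in_vivo", "in_vitro", "in_vivo"))
}

test_that("filter_interactions applies evidence and cohort rules, merges duplicates", {
  edges <- ppi_fixture()
  cohort <- c("X", "P", "Q")
  kept <- filter_interactions(edges, cohort)
  # (X,Y) high-throughput-only line merged with the in_vitro line -> kept once
  expect_equal(nrow(kept), 4)
  xy <- kept[kept$protein_a == "X" & kept$protein_b == "Y", ]
  expect_equal(nrow(xy), 1)
  expect_setequal(xy$evidence[[1]],
                  c("high_throughput", "in_vitro", "yeast_two_hybrid"))
  # weak-evidence-only edge removed
  weak <- filter_interactions(
    tibble::tibble(protein_a = "X", protein_b = "Y",
                   evidence = list("high_throughput")), cohort)
  expect_equal(nrow(weak), 0)
  # no-cohort-endpoint edge removed
  out <- filter_interactions(
    tibble::tibble(protein_a = "U", protein_b = "V",
                   evidence = list("in_vivo")), cohort)
  expect_equal(nrow(out), 0)
})

test_that("count_partners counts distinct partners; self-interaction counts once", {
  edges <- filter_interactions(ppi_fixture(), c("X", "P", "Q"))
  expect_equal(count_partners("P", edges), 2)   # A and B, duplicate-free
  expect_equal(count_partners("Z", edges), 0)
  expect_equal(count_partners("Q", edges), 1)   # self-interaction
})

test_that("select_top_bpi ranks by partner count with lexicographic ties", {
  edges <- tibble::tibble(
    protein_a = c("A", "A", "A", "A", "A", "C", "C", "C", "B", "B", "B"),
    protein_b = c(paste0("p", 1:5), "q1", "q2", "q3", "r1", "r2", "r3"),
    evidence = list("in_vivo")[rep(1, 11)])
  f <- filter_interactions(edges, c("A", "B", "C"))
  expect_equal(select_top_bpi(f, 2), c("A", "B"))  # B before C on tie
  expect_equal(
    select_top_bpi(filter_interactions(edges[0, ], "A"), 5), character(0))
})

test_that("a 16-partner hub exceeds the 15-partner discriminating cut", {
  star <- tibble::tibble(protein_a = "H", protein_b = paste0("n", 1:16),
                         evidence = list("in_vivo")[rep(1, 16)])
  f <- filter_interactions(star, "H")
  expect_equal(count_partners("H", f), 16)
  expect_gt(count_partners("H", f), 15)
})

go_block_fixture <- function() {
  g <- diamond_ontology()
  genes <- tibble::tibble(gene = c("g1", "g2", "g3"),
                          class = c("ageing", "non_ageing", "non_ageing"),
                          pathway = "ber", ka_ki = c(0.1, 0.2, NA))
  ann <- tibble::tibble(gene = c("g1", "g2", "g3"),
                        go_id = c("D", "B", "B"))
  list(graph = g, genes = genes, ann = ann)
}

test_that("build_go_block applies the occurrence threshold inclusively", {
  fx <- go_block_fixture()
  # closures: g1 -> {A,B,C,D}; g2,g3 -> {A,B}; counts: A=3,B=3,C=1,D=1
  blk3 <- build_go_block(fx$genes, fx$ann, fx$graph, go_threshold = 3)
  expect_setequal(setdiff(names(blk3), "gene"), c("A", "B"))  # boundary kept
  blk1 <- build_go_block(fx$genes, fx$ann, fx$graph, go_threshold = 1)
  expect_setequal(setdiff(names(blk1), "gene"), c("A", "B", "C", "D"))
  expect_equal(blk1$D, c("yes", "no", "no"))
})

test_that("raising the threshold never adds GO columns and yes-sets equal closures", {
  co <- generate_cohort(synthetic_config(n_genes = 50, n_positive = 12,
                                         n_terms = 80), seed = 5)
  widths <- vapply(c(1, 3, 7, 11), function(t)
    ncol(build_go_block(co$genes, co$annotations, co$ontology, t)) - 1L,
    integer(1))
  expect_true(all(diff(widths) <= 0))

  blk <- build_go_block(co$genes, co$annotations, co$ontology, 3)
  surviving <- setdiff(names(blk), "gene")
  for (i in c(1, 10, 25)) {
    g <- blk$gene[i]
    closed <- close_annotation(
      co$ontology, co$annotations$go_id[co$annotations$gene == g])
    yes_set <- surviving[blk[i, surviving] == "yes"]
    expect_setequal(yes_set, intersect(closed, surviving))
  }
})

test_that("deduplicate_instances keeps first duplicates, retains class conflicts", {
  base <- tibble::tibble(gene = c("a", "b", "c", "d"),
                         class = c("ageing", "ageing", "ageing", "ageing"),
                         x = c(1, 1, 1, 2), b1 = c("yes", "yes", "yes", "no"))
  out <- deduplicate_instances(base)
  expect_equal(out$gene, c("a", "d"))          # three identical -> first
  expect_equal(deduplicate_instances(out), out)  # idempotent

  conflict <- tibble::tibble(gene = c("a", "b"),
                             class = c("ageing", "non_ageing"),
                             x = c(1, 1))
  expect_warning(kept <- deduplicate_instances(conflict), "conflicting")
  expect_equal(nrow(kept), 2)

  clean <- random_dataset(20, seed = 1)
  expect_equal(deduplicate_instances(clean), clean)
})

test_that("build_dataset honours the variant contracts", {
  co <- generate_cohort(synthetic_config(n_genes = 60, n_positive = 14,
                                         n_terms = 80), seed = 2)
  d1 <- build_dataset(co$genes, co$annotations, co$interactions,
                      co$ontology, variant = "D1")
  expect_false("n_partners" %in% names(d1))
  expect_false(any(grepl("_interaction$", names(d1))))

  d2 <- build_dataset(co$genes, co$annotations, co$interactions,
                      co$ontology, variant = "D2")
  expect_true("n_partners" %in% names(d2))
  expect_false(any(grepl("_interaction$", names(d2))))

  d4 <- build_dataset(co$genes, co$annotations, co$interactions,
                      co$ontology, variant = "D4")
  expect_equal(sum(grepl("_interaction$", names(d4))), 20)

  # nested column sets D1 < D2 < D3 < D4 < D5 at fixed threshold
  cols <- lapply(c("D1", "D2", "D3", "D4", "D5"), function(v)
    names(build_dataset(co$genes, co$annotations, co$interactions,
                        co$ontology, variant = v)))
  for (i in 1:4) expect_true(all(cols[[i]] %in% cols[[i + 1]]))

  single <- co$genes[co$genes$class == "ageing", ]
  expect_error(build_dataset(single, co$annotations, co$interactions,
                             co$ontology), "both classes")
})

test_that("build_dataset removes attribute-identical duplicate genes", {
  fx <- go_block_fixture()
  genes <- tibble::tibble(
    gene = sprintf("g%02d", 1:12),
    class = rep(c("ageing", "non_ageing"), c(4, 8)),
    pathway = rep(c("ber", "ner"), 6),
    ka_ki = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.1, 1.1))
  # genes g11 and g12 identical on every attribute and class
  genes$pathway[11:12] <- "ber"
  ann <- tibble::tibble(gene = c("g01", "g02"), go_id = c("D", "B"))
  edges <- tibble::tibble(protein_a = character(0),
                          protein_b = character(0), evidence = list())
  ds <- build_dataset(genes, ann, edges, fx$graph, variant = "D1",
                      go_threshold = 1)
  expect_equal(nrow(ds), 11)
  expect_false("g12" %in% ds$gene)
})

test_that("build_expression_dataset averages probes per anatomy category", {
  probes <- tibble::tibble(
    gene = c("g1", "g1", "g1", "g2"),
    probe = c("p1", "p2", "p1", "p3"),
    anatomy_category = c("liver", "liver", "brain", "liver"),
    value = c(100, 200, 50, 7))
  genes <- tibble::tibble(gene = c("g1", "g2"),
                          class = c("ageing", "non_ageing"))
  ds <- build_expression_dataset(probes, genes)
  expect_equal(ds$liver, c(150, 7))       # two-point mean, single probe
  expect_equal(ds$brain, c(50, NA))       # no probe -> missing cell
  expect_error(build_expression_dataset(probes[0, ], genes), "empty")
})

test_that("the generated expression dataset has one column per anatomy category", {
  co <- generate_cohort(synthetic_config(), seed = 4)
  ex <- build_expression_dataset(co$probes, co$genes)
  expect_equal(ncol(ex) - 2L, 108)
  expect_true("T_lymphocyte" %in% names(ex))
})
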