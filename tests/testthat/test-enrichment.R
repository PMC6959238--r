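toy_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("GMT parsing handles duplicates and malformed lines", {
  db <- load_gmt(toy_gmt(c("pw1\tfirst pathway\tC1\tC2\tC3",
                           "pw2\tsecond\tC2\tC2\tC4")))
  expect_length(db$sets, 2)
  expect_equal(db$sets$pw1, c("C1", "C2", "C3"))
  expect_equal(db$sets$pw2, c("C2", "C4"))   # duplicate collapsed
  expect_error(load_gmt(toy_gmt(c("pw1\tdesc\tC1", "bad\tonlydesc"))),
               "line 2")
  ## round trip
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db, path)
  expect_equal(load_gmt(path)$sets, db$sets)
})

test_that("hypergeometric enrichment matches exact closed forms", {
  universe <- paste0("C", 1:20)
  db <- structure(list(sets = list(pw = paste0("C", 1:5)),
                       description = c(pw = ""), source = "toy"),
                  class = "pathway_db")
  ## all 5 selected are the whole pathway: p = 1 / choose(20, 5)
  res <- ora_hypergeometric(paste0("C", 1:5), universe, db)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k, 5)
  ## selected = universe: k = K, p = 1
  res_all <- ora_hypergeometric(universe, universe, db)
  expect_equal(res_all$k, res_all$K)
  expect_equal(res_all$p_value, 1)
  expect_error(ora_hypergeometric(c("C1", "ZZZ"), universe, db), "outside")
})

test_that("enrichment p-values equal the pmf-summation oracle", {
  pmf_oracle <- function(N, K, n, k)
    sum(vapply(k:min(K, n), function(x)
      choose(K, x) * choose(N - K, n - x) / choose(N, n), numeric(1)))
  set.seed(10)
  for (i in 1:40) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- paste0("C", 1:N)
    selected <- sample(universe, n)
    db <- structure(list(sets = list(pw = universe[1:K]),
                         description = c(pw = ""), source = "toy"),
                    class = "pathway_db")
    res <- ora_hypergeometric(selected, universe, db)
    expect_equal(res$p_value, pmf_oracle(N, K, n, res$k), tolerance = 1e-12)
  }
})

test_that("enrichment p is monotone decreasing in the overlap", {
  p <- vapply(0:5, function(k)
    stats::phyper(k - 1, 5, 15, 5, lower.tail = FALSE), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("pathways outside the universe are restricted or skipped", {
  universe <- paste0("C", 1:10)
  db <- structure(list(sets = list(inpw = c("C1", "C2", "X9"),
                                   outpw = c("X1", "X2")),
                       description = c(inpw = "", outpw = ""), source = "toy"),
                  class = "pathway_db")
  res <- ora_hypergeometric(c("C1", "C3"), universe, db)
  expect_equal(res$pathway, "inpw")
  expect_equal(res$K, 2)   # X9 not measurable
})

test_that("compound-gene network builds degrees and flags unmapped compounds", {
  mapping <- data.frame(compound_id = c("M1", "M1", "M2", "M1"),
                        gene_id = c("G1", "G2", "G1", "G1"))
  net <- build_compound_gene_network(c("M1", "M2", "M3"), mapping)
  expect_equal(net$compound_degree[["M1"]], 2)   # duplicate edge collapsed
  expect_equal(net$compound_degree[["M2"]], 1)
  expect_equal(net$compound_degree[["M3"]], 0)
  expect_equal(net$unmapped, "M3")
  expect_equal(nrow(net$edges), 3)
  expect_true(igraph::is_bipartite(net$graph))
  expect_error(build_compound_gene_network("M1", mapping[0, ]), "empty")
})

test_that("hubs are compounds linked to more than one gene, deterministically ordered", {
  mapping <- data.frame(
    compound_id = c(rep("M5", 5), rep("Ma", 3), rep("Mb", 3), "M1"),
    gene_id = c(paste0("G", 1:5), paste0("G", 6:8), paste0("G", 9:11), "G1"))
  net <- build_compound_gene_network(c("M5", "Ma", "Mb", "M1"), mapping)
  hubs <- find_hubs(net)
  expect_equal(hubs$compound_id, c("M5", "Ma", "Mb"))  # M1 degree 1: no hub
  expect_equal(hubs$degree, c(5, 3, 3))                # ID tie-break Ma < Mb
  empty <- build_compound_gene_network("Zz", mapping)
  expect_equal(nrow(find_hubs(empty)), 0)
  ## invariance to edge-row order
  net2 <- build_compound_gene_network(c("M5", "Ma", "Mb", "M1"),
                                      mapping[sample(nrow(mapping)), ])
  expect_equal(find_hubs(net2), hubs)
})

test_that("shared hubs are intersected across groups with provenance", {
  got <- shared_hubs(list(g1 = c("A", "B"), g2 = c("B", "C"),
                          g3 = c("B", "D")))
  expect_equal(got$pairwise$g1_x_g2, "B")
  expect_equal(got$global, "B")
  expect_equal(got$by_hub$groups[got$by_hub$compound_id == "B"], "g1;g2;g3")
  none <- shared_hubs(list(g1 = "A", g2 = "B"))
  expect_length(none$global, 0)
  expect_equal(nrow(none$by_hub), 0)
  expect_error(shared_hubs(list(g1 = "A")), "at least 2")
})
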