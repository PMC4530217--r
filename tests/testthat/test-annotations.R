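test_that("dN/dS loader computes ratios and handles degenerate rows", {
  f <- tempfile()
  write.table(data.frame(gene_id = c("g1", "g2", "g3"),
                         dn = c(0.01, 0.2, 0.1), ds = c(0.10, 0, 0.5)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  v <- load_dnds(f)
  expect_equal(unname(v["g1"]), 0.1)
  expect_true(is.na(v["g2"]))            # ds = 0 -> absent
  expect_equal(attr(v, "n_ds_zero"), 1L)
  # universe restriction: set-difference oracle
  set.seed(2)
  ids <- sprintf("g%02d", 1:20)
  write.table(data.frame(gene_id = ids, dn = runif(20), ds = runif(20) + 0.1),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  uni <- ids[1:17]
  v <- load_dnds(f, universe = uni)
  expect_identical(names(v), intersect(ids, uni))
  expect_equal(attr(v, "n_outside"), 3L)
  write.table(data.frame(gene_id = "g1", dn = -0.1, ds = 0.2),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_dnds(f), "negative")
})

test_that("gene ages map the lineage ladder onto the four intervals", {
  expect_equal(classify_gene_age("Bilateria"), "Opisthokonta-Bilateria")
  expect_equal(classify_gene_age("Chordata"), "Chordata-Euteleostomi")
  expect_equal(classify_gene_age("Amniota"), "Sarcopterygii-Amniota")
  expect_equal(classify_gene_age("Eutheria"), "Mammalia-Eutheria")
  expect_true(is.na(classify_gene_age("Homo sapiens")))   # excluded: too young
  expect_true(is.na(classify_gene_age("Primates")))
  expect_error(classify_gene_age("Dinosauria"), "Dinosauria")
  # total over the declared lineage, pure lookup
  lineage <- c("Opisthokonta", "Eumetazoa", "Bilateria", "Chordata",
               "Vertebrata", "Euteleostomi", "Sarcopterygii", "Tetrapoda",
               "Amniota", "Mammalia", "Theria", "Eutheria")
  out <- classify_gene_age(lineage)
  expect_false(any(is.na(out)))
  expect_identical(out, classify_gene_age(lineage))
  expect_true(all(out %in% age_intervals()))
})

test_that("ortholog classes follow the bipartite component shape", {
  uni <- c("H1", "H2", "H3")
  # one-to-one
  p <- data.frame(human_gene = "H1", zebrafish_gene = "Z1")
  expect_equal(unname(classify_orthologs(p, uni)),
               c("one2one", "new_gene", "new_gene"))
  # one-to-many: H1 against two zebrafish genes
  p <- data.frame(human_gene = c("H1", "H1"), zebrafish_gene = c("Z1", "Z2"))
  expect_equal(unname(classify_orthologs(p, uni)["H1"]), "one2many")
  # duplications on both sides: H1, H2 both many2many
  p <- data.frame(human_gene = c("H1", "H2", "H1"),
                  zebrafish_gene = c("Z1", "Z1", "Z2"))
  cls <- classify_orthologs(p, uni)
  expect_equal(unname(cls[c("H1", "H2")]), c("many2many", "many2many"))
  expect_equal(unname(cls["H3"]), "new_gene")
  # duplicates deduplicated with a warning
  p <- data.frame(human_gene = c("H1", "H1"), zebrafish_gene = c("Z1", "Z1"))
  expect_warning(cls <- classify_orthologs(p, uni), "duplicate")
  expect_equal(unname(cls["H1"]), "one2one")
})

test_that("ortholog classes partition the gene universe", {
  set.seed(8)
  cfg <- synthetic_config(n_genes = 400, seed = 8)
  gx <- generate_expression(cfg)
  an <- generate_annotations(gx$truth, cfg)
  cls <- classify_orthologs(an$homology, gx$truth$gene_id)
  expect_equal(sum(table(cls)), 400L)
  expect_true(all(cls %in% c("one2one", "one2many", "many2many", "new_gene")))
})

test_that("TF flags require GO:0006355", {
  go <- data.frame(gene_id = c("g1", "g2", "g2"),
                   go_id = c("GO:0006355", "GO:0008150", "GO:0003700"))
  f <- flag_tfs(go, c("g1", "g2", "g3"))
  expect_equal(unname(f), c(TRUE, FALSE, FALSE))
  expect_false(any(flag_tfs(go[0, ], c("g1", "g2"))))
})

test_that("promoter HCNE windows respect strand and half-open overlap", {
  loci <- data.frame(gene_id = c("plus", "edge", "minus"),
                     chrom = "chr1", tss = c(10000L, 10000L, 10000L),
                     strand = c("+", "+", "-"))
  hc <- data.frame(chrom = "chr1",
                   start = c(9400L, 8000L, 10400L),
                   end = c(9600L, 9500L, 10600L),
                   identity = c(95, 95, 95))
  f <- flag_hcne(loci, hc[1, ])
  expect_true(f[["plus"]])                 # [9400,9600) meets [9500,10000)
  f <- flag_hcne(loci[2, ], hc[2, ])
  expect_false(f[["edge"]])                # end == window start: half-open
  f <- flag_hcne(loci[3, ], hc[3, ])
  expect_true(f[["minus"]])                # [10400,10600) meets [10000,10500)
  # invariant to interval order and to splitting into abutting halves
  many <- rbind(hc, hc[3:1, ])
  split2 <- data.frame(chrom = "chr1", start = c(9400L, 9500L),
                       end = c(9500L, 9600L), identity = c(95, 95))
  expect_equal(flag_hcne(loci, many), flag_hcne(loci, many[sample(6), ]))
  expect_equal(flag_hcne(loci[1, ], split2)[["plus"]],
               flag_hcne(loci[1, ], hc[1, ])[["plus"]])
  expect_error(flag_hcne(loci, data.frame(chrom = "chr1", start = 1,
                                          end = 10, identity = 80)),
               "identity")
})

test_that("annotation assembly aligns everything on the universe", {
  uni <- c("a", "b", "c")
  tab <- gene_annotation_table(
    uni, dnds = c(a = 0.1, b = 0.2),
    age_interval = c(a = "Mammalia-Eutheria"),
    ortholog_class = c(a = "one2one", b = "new_gene", c = "one2many"),
    is_tf = c(a = TRUE, b = FALSE, c = FALSE))
  expect_identical(rownames(tab), uni)
  expect_true(is.na(tab["c", "dnds"]))
  expect_true(is.na(tab["b", "age_interval"]))
  expect_error(gene_annotation_table("a", dnds = c(a = -1)), "negative")
})
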