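fixture_tables <- function() {
  read_terminology_tables(
    system.file("extdata", "veddra-synthetic.tsv", package = "vetgrade"),
    system.file("extdata", "atcvet-synthetic.tsv", package = "vetgrade"),
    system.file("extdata", "spc-synthetic.tsv", package = "vetgrade"))
}

test_that("event coding is exact-after-normalization with UNMAPPED markers", {
  tables <- fixture_tables()
  coded <- code_events(c("vomiting", "Vomiting ", "purple spots"), tables)
  expect_equal(coded$llt_name, c("Vomiting", "Vomiting", "UNMAPPED"))
  expect_equal(coded$soc[1:2], rep("Digestive tract disorders", 2))
  expect_equal(coded$term[3], "purple spots")

  empty <- terminology_tables()
  expect_true(all(code_events("vomiting", empty)$llt_code == "UNMAPPED"))
})

test_that("terminology keys must be unique after normalization", {
  expect_error(terminology_tables(
    veddra = data.frame(term = c("Vomiting", "vomiting "),
                        llt_code = c("1", "2"), llt_name = c("a", "b"),
                        soc = c("x", "y"))), "not unique")
})

test_that("drug-event pair enumeration counts report x suspect product", {
  r1 <- minimal_report("A")
  r3 <- minimal_report("B", suspect_drugs = list(
    drug_entry("X"), drug_entry("Y"), drug_entry("Z")))
  pairs <- enumerate_pairs(list(r1, r3))
  expect_equal(nrow(pairs), 4)
  expect_equal(nrow(enumerate_pairs(list())), 0)
  # invariant under corpus permutation
  expect_equal(nrow(enumerate_pairs(list(r3, r1))), 4)
  # a 59-report corpus with 76 products yields 76 pairs
  set.seed(5)
  reports <- lapply(1:59, function(i) {
    n_drugs <- if (i <= 17) 2 else 1  # 17*2 + 42 = 76
    minimal_report(sprintf("R%02d", i), suspect_drugs = lapply(
      seq_len(n_drugs), function(k) drug_entry(sprintf("Prod%d", k))))
  })
  expect_equal(nrow(enumerate_pairs(reports)), 76)
})

test_that("expectedness requires every event term listed in the SPC", {
  tables <- fixture_tables()
  mk <- function(product, desc) enumerate_pairs(list(minimal_report(
    "P", suspect_drugs = list(drug_entry(product)),
    reaction_description = desc)))
  expect_equal(classify_expectedness(mk("Vaccamune DHP", "lethargy"),
                                     tables)$expectedness, "EXPECTED")
  expect_equal(classify_expectedness(
    mk("Vaccamune DHP", "lethargy; seizure"), tables)$expectedness,
    "UNEXPECTED")
  expect_equal(classify_expectedness(mk("Herbal Soothe Balm", "vomiting"),
                                     tables)$expectedness, "UNASSESSABLE")
})

test_that("enlarging an SPC never converts expected to unexpected", {
  base_spc <- data.frame(product = "Vaccamune DHP",
                         listed_term = c("lethargy", "vomiting"))
  tables_small <- terminology_tables(spc = base_spc)
  tables_big <- terminology_tables(spc = rbind(
    base_spc, data.frame(product = "Vaccamune DHP", listed_term = "pyrexia")))
  descs <- c("lethargy", "vomiting; lethargy", "pyrexia", "seizure")
  for (d in descs) {
    p <- enumerate_pairs(list(minimal_report(
      "P", suspect_drugs = list(drug_entry("Vaccamune DHP")),
      reaction_description = d)))
    small <- classify_expectedness(p, tables_small)$expectedness
    big <- classify_expectedness(p, tables_big)$expectedness
    if (small == "EXPECTED") expect_equal(big, "EXPECTED", info = d)
  }
})

test_that("product grouping counts pairs and reports percentages of total", {
  tables <- fixture_tables()
  # 49 immunological pairs of 76 is 64.5%, computed from the counts
  reports <- c(
    lapply(1:49, function(i) minimal_report(
      sprintf("I%02d", i),
      suspect_drugs = list(drug_entry("Vaccamune DHP")))),
    lapply(1:26, function(i) minimal_report(
      sprintf("O%02d", i),
      suspect_drugs = list(drug_entry("Parashield Spot-On")))),
    list(minimal_report("U1",
                        suspect_drugs = list(drug_entry("Mystery Tonic")))))
  grp <- group_products(enumerate_pairs(reports), tables)
  expect_equal(sum(grp$count), 76)
  expect_equal(grp$count[grp$group == "Immunologicals"], 49L)
  expect_equal(grp$percent[grp$group == "Immunologicals"], 100 * 49 / 76,
               tolerance = 1e-12)
  expect_equal(round(grp$percent[grp$group == "Immunologicals"], 1), 64.5)
  expect_equal(grp$count[grp$group == "Unknown"], 1L)
  expect_equal(sum(grp$percent), 100, tolerance = 0.1)

  single <- group_products(enumerate_pairs(list(minimal_report("S"))),
                           tables)
  expect_equal(single$percent, 100)
  all_unmapped <- group_products(
    enumerate_pairs(list(minimal_report(
      "S", suspect_drugs = list(drug_entry("Nope"))))),
    terminology_tables())
  expect_identical(all_unmapped$group, "Unknown")
  expect_equal(all_unmapped$percent, 100)
})
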