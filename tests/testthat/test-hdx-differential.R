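test_that("difference classification matches an if-chain oracle, boundaries included", {
  deltas <- c(seq(-2, 2, by = 0.01), -1.0, -0.5, 0, 0.5, 1.0,
              0.4999, 0.5001, 0.9999, 1.0001)
  got <- as.character(classify_difference(deltas))
  expect_equal(got, oracle_classify(deltas))
  # spot values: the documented category assignments
  expect_equal(as.character(classify_difference(0.7)), "modest_increase")
  expect_equal(as.character(classify_difference(-1.3)), "major_decrease")
  expect_equal(as.character(classify_difference(1.0)), "modest_increase")
  expect_equal(as.character(classify_difference(0.5)), "modest_increase")
})

test_that("custom thresholds shift the category boundaries", {
  thr <- hdx_thresholds(modest = 0.3, major = 0.8)
  expect_equal(as.character(classify_difference(c(0.4, 0.9), thr)),
               c("modest_increase", "major_increase"))
  expect_error(hdx_thresholds(modest = 1, major = 0.5))
})

test_that("self-difference is identically zero and category none", {
  sc <- hdx_t316a_scenario(seed = 2)
  dm <- difference_map(sc, "WT", "WT")
  expect_true(all(dm$delta == 0))
  expect_true(all(dm$category == "none"))
})

test_that("swapping state and reference negates deltas exactly", {
  sc <- hdx_t316a_scenario(seed = 2)
  ab <- difference_map(sc, "T316A", "WT")
  ba <- difference_map(sc, "WT", "T316A")
  key <- function(d) paste(d$peptide_id, d$time)
  ba <- ba[match(key(ab), key(ba)), ]
  expect_equal(ab$delta, -ba$delta)
  mirror <- c(major_decrease = "major_increase",
              modest_decrease = "modest_increase", none = "none",
              modest_increase = "modest_decrease",
              major_increase = "major_decrease")
  expect_equal(as.character(ab$category),
               unname(mirror[as.character(ba$category)]))
})

test_that("missing time points are skipped with a message", {
  sc <- hdx_t316a_scenario(seed = 2)
  pid <- sc$peptide_id[1]
  broken <- sc[!(sc$state == "T316A" & sc$peptide_id == pid &
                   sc$time == 600), ]
  peps <- curate_coincident(list(broken[broken$state == "WT", ],
                                 broken[broken$state == "WT", ]))
  expect_message(dm <- difference_map(broken, "T316A", "WT", peptides = peps),
                 "skipped")
  expect_false(any(dm$peptide_id == pid & dm$time == 600))
})

test_that("consolidation applies the shortest-covering-peptide rule", {
  diffs <- tibble::tibble(
    peptide_id = c("P1", "P2"),
    sequence = c("AAAAAAAAAAAAAAAA", "AAAAAAAA"),
    start = c(10L, 10L), end = c(25L, 17L),
    time = 600, delta = c(1.2, 0.1),
    category = classify_difference(c(1.2, 0.1)))
  ann <- consolidate_residues(diffs)
  expect_equal(ann$residue, 10:25)
  expect_equal(as.character(ann$category[ann$residue <= 17]),
               rep("none", 8))
  expect_equal(as.character(ann$category[ann$residue >= 18]),
               rep("major_increase", 8))
  expect_true(all(vapply(ann$supporting_peptides[ann$residue <= 17],
                         function(p) identical(p, c("P1", "P2")),
                         logical(1))))
})

test_that("ties on peptide length resolve by larger |delta| then lower start", {
  diffs <- tibble::tibble(
    peptide_id = c("A", "B"),
    sequence = c("AAAAAA", "AAAAAA"),
    start = c(1L, 3L), end = c(6L, 8L),
    time = 60, delta = c(0.2, 1.5),
    category = classify_difference(c(0.2, 1.5)))
  ann <- consolidate_residues(diffs)
  # residues 3-6 covered by both same-length peptides; B has larger |delta|
  expect_equal(as.character(ann$category[ann$residue %in% 3:6]),
               rep("major_increase", 4))
  # equal |delta| ties break toward the lower start
  diffs$delta <- c(0.2, 0.2)
  diffs$category <- classify_difference(diffs$delta)
  ann2 <- consolidate_residues(diffs)
  expect_equal(ann2$peptide_id[ann2$residue == 4], "A")
})

test_that("per-peptide category uses the strongest-|delta| time point", {
  diffs <- tibble::tibble(
    peptide_id = "P1", sequence = "AAAAAA", start = 1L, end = 6L,
    time = c(10, 600, 3600), delta = c(0.1, -1.4, 0.6),
    category = classify_difference(c(0.1, -1.4, 0.6)))
  ann <- consolidate_residues(diffs)
  expect_true(all(ann$category == "major_decrease"))
})

test_that("zero-delta peptide consolidates to all-none residues", {
  diffs <- tibble::tibble(
    peptide_id = "P1", sequence = "AAAAAA", start = 1L, end = 6L,
    time = c(10, 600), delta = c(0, 0),
    category = classify_difference(c(0, 0)))
  ann <- consolidate_residues(diffs)
  expect_equal(ann$residue, 1:6)
  expect_true(all(ann$category == "none"))
})

test_that("planted perturbation stays inside the peptide-overlap envelope", {
  seqc <- synthetic_btk_sequence()
  closed <- baseline_closed_profile(seqc)
  map <- generate_peptide_map(seqc, mean_length = 12, min_overlap = 3,
                              seed = 659)
  region <- c(215L, 280L)
  envelope <- unlist(Map(seq.int,
                         map$start[map$end >= region[1] & map$start <= region[2]],
                         map$end[map$end >= region[1] & map$start <= region[2]]))
  for (seed in 1:20) {
    ens <- build_two_state_ensemble(closed, list(region), 1.5, f_open = 1)
    ref <- conformational_ensemble(list(closed), 1)
    cond_s <- exchange_conditions(noise_sd = 0.05, seed = seed)
    cond_r <- exchange_conditions(noise_sd = 0.05, seed = seed + 5000L)
    tab <- dplyr::bind_rows(
      simulate_uptake_table(ens, map, cond_s, "open"),
      simulate_uptake_table(ref, map, cond_r, "apo"))
    dm <- difference_map(tab, "open", "apo")
    ann <- consolidate_residues(dm, map)
    inc <- ann$residue[ann$category %in% c("modest_increase",
                                           "major_increase")]
    expect_true(all(inc %in% envelope))
    covered_planted <- intersect(region[1]:region[2], ann$residue)
    expect_gte(mean(covered_planted %in% inc), 0.8)
  }
})

test_that("domain summary counts categories per region with zero-fill", {
  empty <- consolidate_residues(tibble::tibble(
    peptide_id = character(0), sequence = character(0),
    start = integer(0), end = integer(0), time = numeric(0),
    delta = numeric(0), category = classify_difference(numeric(0))))
  ds <- domain_summary(empty)
  expect_true(all(ds$n_residues == 0))
  expect_setequal(unique(ds$domain),
                  c(btk_domains()$domain, "unassigned"))

  ann <- tibble::tibble(
    residue = c(220L, 221L, 500L), category = factor(
      c("modest_increase", "major_increase", "major_decrease"),
      levels = levels(classify_difference(0))),
    peptide_id = "p", supporting_peptides = list("p", "p", "p"))
  ds2 <- domain_summary(ann)
  expect_equal(ds2$n_residues[ds2$domain == "SH3" &
                                ds2$category == "modest_increase"], 1L)
  expect_equal(sum(ds2$n_residues[ds2$domain == "kinase"]), 1L)
})

test_that("residues outside all domains count as unassigned", {
  ann <- tibble::tibble(
    residue = 700L, category = classify_difference(1.2),
    peptide_id = "p", supporting_peptides = list("p"))
  ds <- domain_summary(ann)
  expect_equal(sum(ds$n_residues[ds$domain == "unassigned"]), 1L)
})

test_that("drug panel reproduces the two-category inhibitor split", {
  panel <- hdx_drug_panel(seed = 17)
  map <- attr(panel, "peptide_map")
  peps <- curate_coincident(split(panel, panel$state))
  calls <- vapply(setdiff(unique(panel$state), "apo"), function(d) {
    dm <- difference_map(panel, d, "apo", peptides = peps)
    classify_inhibitor_response(domain_summary(consolidate_residues(dm, map)))
  }, character(1))
  expect_equal(unname(calls[c("ibrutinib_like", "dasatinib_like")]),
               rep("regulatory_displacing", 2))
  expect_equal(unname(calls[c("gdc_like", "cgi_like", "cc292_like")]),
               rep("kinase_local", 3))
})

test_that("ibrutinib-like map shows kinase protection and regulatory exposure", {
  panel <- hdx_drug_panel(seed = 8)
  dm <- difference_map(panel, "ibrutinib_like", "apo")
  kin <- dm[dm$start >= 430 & dm$end <= 520, ]
  reg <- dm[dm$start >= 215 & dm$end <= 396, ]
  expect_lt(min(tapply(kin$delta, kin$peptide_id, min)), -0.5)
  expect_true(all(tapply(reg$delta, reg$peptide_id, max) > 0))
})

test_that("kinase-local drugs leave regulatory domains without increases", {
  panel <- hdx_drug_panel(seed = 9)
  map <- attr(panel, "peptide_map")
  ds <- domain_summary(consolidate_residues(
    difference_map(panel, "gdc_like", "apo"), map))
  inc <- ds$category %in% c("modest_increase", "major_increase")
  expect_equal(sum(ds$n_residues[ds$domain %in% c("SH3", "SH2", "linker") &
                                   inc]), 0L)
})

test_that("dasatinib displaces the regulatory domains more than ibrutinib", {
  panel <- hdx_drug_panel(seed = 10)
  map <- attr(panel, "peptide_map")
  major_reg <- function(d) {
    ds <- domain_summary(consolidate_residues(
      difference_map(panel, d, "apo"), map))
    sum(ds$n_residues[ds$domain %in% c("SH3", "SH2", "linker") &
                        ds$category == "major_increase"])
  }
  expect_gt(major_reg("dasatinib_like"), major_reg("ibrutinib_like"))
})

test_that("inhibitor response classification handles edge inputs", {
  ds <- domain_summary(consolidate_residues(tibble::tibble(
    peptide_id = character(0), sequence = character(0),
    start = integer(0), end = integer(0), time = numeric(0),
    delta = numeric(0), category = classify_difference(numeric(0)))))
  expect_equal(classify_inhibitor_response(ds), "no_effect")
  expect_error(classify_inhibitor_response(ds, regulatory_labels = "XX"),
               "unknown domain")
})
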