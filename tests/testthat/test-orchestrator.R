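# The create_phenotypes driver: end-to-end behaviour, output files,
# determinism and log consistency.

listing_style_sim <- function(g, out = NULL, rep = 2, seed = 55, ...) {
  create_phenotypes(
    g, architecture = "spurious_pleiotropy", ntraits = 2, add_QTN_num = 3,
    add_effect = list(c(0.2, 0.1, 0.05), c(0.3, 0.2, 0.1)), h2 = c(0.5, 0.5),
    ld = 0.7, type_of_ld = "indirect", rep = rep, seed = seed, out = out, ...
  )
}

test_that("a two-trait spurious simulation produces phenotypes and provenance", {
  g <- block_fixture(n = 200, m = 400, r = 0.6, seed = 61)
  out <- withr::local_tempdir()
  sim <- listing_style_sim(g, out = out, remove_QTN = TRUE,
                           output_format = c("wide_table", "gemma"))
  expect_equal(dim(sim$phenotypes[[1]]), c(200, 2))
  # provenance tables follow the documented schemas
  expect_named(sim$qtn_map, c("Replication", "Marker_type", "Marker",
                              "Allele", "Chromosome", "Position", "cM",
                              "MAF"))
  expect_setequal(unique(sim$qtn_map$Marker_type),
                  c("cause_of_LD", "QTN_upstream", "QTN_downstream"))
  expect_named(sim$ld_summary,
               c("Replication", "Marker_causing_LD", "input_LD",
                 "Actual_LD_with_QTN_of_Trait_1",
                 "Actual_LD_with_QTN_of_Trait_2", "QTN_for_Trait_1",
                 "QTN_for_Trait_2", "LD_between_QTNs"))
  expect_true(all(abs(sim$ld_summary$Actual_LD_with_QTN_of_Trait_1) <= 0.7))
  expect_true(file.exists(file.path(out, "simulation_log.txt")))
  expect_true(file.exists(file.path(out, "seeds.txt")))

  # marker export drops each distinct QTN but keeps linking markers
  qtn_ids <- unique(sim$qtn_map$Marker[sim$qtn_map$Marker_type !=
                                         "cause_of_LD"])
  link_ids <- unique(sim$qtn_map$Marker[sim$qtn_map$Marker_type ==
                                          "cause_of_LD"])
  g2 <- read_genotypes(file.path(out, "markers_no_qtn.numeric.txt"),
                       "numeric")
  expect_equal(ncol(g2$values), 400 - length(qtn_ids))
  expect_false(any(qtn_ids %in% g2$map$marker_id))
  expect_true(all(link_ids %in% g2$map$marker_id))
})

test_that("phenotype writers follow their format contracts and round-trip", {
  set.seed(88)
  P <- matrix(stats::rnorm(20), 10, 2,
              dimnames = list(paste0("ind", 1:10), c("trait_1", "trait_2")))
  gem <- withr::local_tempfile()
  write_phenotypes(P, gem, "gemma")
  lines <- readLines(gem)
  expect_length(lines, 10) # one line per individual, no header
  expect_length(strsplit(lines[1], " ")[[1]], 2)
  expect_equal(unname(read_phenotypes(gem, "gemma")), unname(P),
               tolerance = 1e-9)

  tas <- withr::local_tempfile()
  write_phenotypes(P, tas, "tassel")
  expect_equal(readLines(tas, n = 1), "<Phenotype>")
  expect_equal(read_phenotypes(tas, "tassel"), P, tolerance = 1e-9)

  wid <- withr::local_tempfile()
  write_phenotypes(P, wid, "wide_table", rep_id = 4)
  expect_equal(unname(read_phenotypes(wid, "wide_table", rep_id = 4)),
               unname(P), tolerance = 1e-9)

  expect_error(write_phenotypes(P, gem, "plink"))
})

test_that("long output covers every trait-replicate combination", {
  g <- make_fixture(40, 120, seed = 63)
  out <- withr::local_tempdir()
  create_phenotypes(g, architecture = "pleiotropy", ntraits = 2,
                    add_QTN_num = 2, add_effect = c(0.3, 0.4), h2 = 0.5,
                    rep = 3, seed = 9, out = out,
                    output_format = "long_table")
  tab <- utils::read.table(file.path(out, "phenotypes_long.txt"),
                           header = TRUE, sep = "\t")
  groups <- unique(tab[, c("rep", "trait")])
  expect_equal(nrow(groups), 6) # 2 traits x 3 replicates
  expect_equal(nrow(tab), 40 * 6)
})

test_that("the whole output directory is byte-identical across reruns", {
  g <- block_fixture(n = 120, m = 300, r = 0.6, seed = 65)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  listing_style_sim(g, out = out1, remove_QTN = TRUE,
                    output_format = c("wide_table", "long_table", "gemma",
                                      "tassel"))
  listing_style_sim(g, out = out2, remove_QTN = TRUE,
                    output_format = c("wide_table", "long_table", "gemma",
                                      "tassel"))
  f1 <- sort(list.files(out1, recursive = TRUE))
  f2 <- sort(list.files(out2, recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = f)
  }
  # a different root seed changes the phenotypes
  out3 <- withr::local_tempdir()
  listing_style_sim(g, out = out3, seed = 56,
                    output_format = "wide_table")
  expect_false(identical(
    readLines(file.path(out1, "phenotypes_wide.txt")),
    readLines(file.path(out3, "phenotypes_wide.txt"))
  ))
})

test_that("logged realized statistics match values recomputed from emitted files", {
  g <- make_fixture(150, 300, seed = 67)
  out <- withr::local_tempdir()
  sim <- create_phenotypes(g, architecture = "pleiotropy", ntraits = 2,
                           add_QTN_num = 3,
                           add_effect = list(c(0.2, 0.1, 0.05),
                                             c(0.3, 0.2, 0.1)),
                           h2 = c(0.3, 0.7), rep = 2, seed = 31, out = out,
                           output_format = "wide_table")
  # realized h2 from the emitted phenotypes and the stored genetic values
  h2_file <- utils::read.table(file.path(out, "realized_h2.txt"),
                               header = TRUE, sep = "\t")
  for (r in 1:2) {
    P <- read_phenotypes(file.path(out, "phenotypes_wide.txt"),
                         "wide_table", rep_id = r)
    G <- sim$genetic_values[[r]]
    E <- P - G
    vg <- apply(G, 2, stats::var)
    ve <- apply(E, 2, stats::var)
    expect_equal(unname(as.matrix(h2_file[r, -1]))[1, ],
                 unname(vg / (vg + ve)), tolerance = 1e-6)
    expect_equal(unname(sim$realized_h2[r, ]), unname(vg / (vg + ve)),
                 tolerance = 1e-9)
  }
})

test_that("heritability 1 with a correlation target yields exactly correlated phenotypes", {
  g <- make_fixture(180, 250, seed = 69)
  target <- matrix(c(1, 0.5, 0.5, 1), 2)
  sim <- create_phenotypes(g, architecture = "pleiotropy", ntraits = 2,
                           add_QTN_num = 4, add_effect = c(0.3, 0.5),
                           h2 = 1, cor = target, rep = 1, seed = 71)
  P <- sim$phenotypes[[1]]
  expect_identical(P, sim$genetic_values[[1]]) # zero noise, bit for bit
  expect_lt(max(abs(stats::cor(P) - target)), 1e-10)
})

test_that("misconfigurations fail fast with named errors", {
  g <- make_fixture(50, 100, seed = 73)
  expect_error(create_phenotypes(g, ntraits = 2, add_QTN_num = 2,
                                 add_effect = c(0.1, 0.2), h2 = 1.5),
               class = "pleiosim_config_error")
  expect_error(create_phenotypes(g, ntraits = 2, add_QTN_num = 2,
                                 add_effect = c(0.1, 0.2),
                                 cor = matrix(c(1, 2, 2, 1), 2)),
               class = "pleiosim_config_error")
  expect_error(create_phenotypes(g, architecture = "spurious_pleiotropy",
                                 ntraits = 3, add_QTN_num = 2,
                                 add_effect = c(0.1, 0.2, 0.3)),
               class = "pleiosim_config_error")
  expect_error(create_phenotypes(g, ntraits = 2, add_QTN_num = 2,
                                 add_effect = c(0.1, 0.2),
                                 output_format = "plink"),
               class = "pleiosim_config_error")
  expect_error(create_phenotypes(g, ntraits = 2, add_QTN_num = 2,
                                 h2 = 0.5),
               class = "pleiosim_config_error") # effects missing
})
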