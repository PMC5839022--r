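test_that("pedigree reading yields one trio per affected child and keeps order", {
  f <- write_lines_tmp(ped_lines_one_trio, ".ped")
  trios <- read_pedigree(f)
  expect_equal(nrow(trios), 1)
  expect_equal(trios$child_id, "T1c")
  expect_equal(trios$father_id, "T1p")
  expect_equal(trios$mother_id, "T1m")
  expect_true(trios$child_affected)
  expect_equal(trios$child_sex, "female")

  three <- unlist(lapply(1:3, function(t) {
    gsub("T1", paste0("T", t), gsub("FAM1", paste0("FAM", t),
                                    ped_lines_one_trio))
  }))
  trios3 <- read_pedigree(write_lines_tmp(three, ".ped"))
  expect_equal(trios3$family_id, c("FAM1", "FAM2", "FAM3"))
  expect_equal(trios3$child_id, c("T1c", "T2c", "T3c"))
})

test_that("pedigree referential integrity and duplicates are hard errors", {
  bad <- c("FAM1 T1c X T1m 2 2", "FAM1 T1m 0 0 2 1")
  expect_error(read_pedigree(write_lines_tmp(bad, ".ped")),
               "absent parent")
  dup <- c(ped_lines_one_trio, "FAM1 T1p 0 0 1 1")
  expect_error(read_pedigree(write_lines_tmp(dup, ".ped")), "duplicate")
})

test_that("biallelic VCF records map to the data model with 1-based positions", {
  body <- paste(c("1", "12345", ".", "A", "G", "5000", "PASS",
                  "ANN=G|missense_variant|MODERATE|GENE1|GENE1|transcript|tx1|protein_coding|1|c.1A>G|p.M1V",
                  "GT:AD:DP:GQ:PL",
                  "0/1:48,52:100:99:1200,0,1300",
                  "0/0:100,0:100:99:0,300,3000",
                  "0/0:99,0:99:99:0,297,2970"), collapse = "\t")
  trios <- read_pedigree(write_lines_tmp(ped_lines_one_trio, ".ped"))
  ds <- read_trio_vcf(write_lines_tmp(tiny_vcf_lines(body), ".vcf"), trios)
  expect_equal(nrow(ds$variants), 1)
  expect_equal(ds$variants$pos, 12345L)
  expect_equal(ds$variants$qual, 5000)
  g <- ds$genotypes
  expect_equal(g$n_alt[g$sample == "T1c"], 1L)
  expect_equal(g$ad_alt[g$sample == "T1c"], 52)
  expect_equal(g$pl1[g$sample == "T1c"], 0)
  expect_equal(ds$annotations$gene_symbol, "GENE1")
  expect_equal(ds$annotations$consequence, "missense")
})

test_that("multi-allelic sites split into biallelic records conserving (site, alt) pairs", {
  # A -> G,T with per-allele AD and a 6-entry PL (genotype order
  # 0/0,0/1,1/1,0/2,1/2,2/2)
  body <- paste(c("1", "500", ".", "A", "G,T", "900", "PASS", ".",
                  "GT:AD:DP:GQ:PL",
                  "1/2:10,45,45:100:99:800,400,600,500,0,700",
                  "0/1:50,50,0:100:99:500,0,600,900,800,1700",
                  "0/2:50,0,50:100:99:600,900,1800,0,700,650"),
                collapse = "\t")
  trios <- read_pedigree(write_lines_tmp(ped_lines_one_trio, ".ped"))
  ds <- read_trio_vcf(write_lines_tmp(tiny_vcf_lines(body), ".vcf"), trios)
  expect_equal(nrow(ds$variants), 2)
  expect_equal(ds$variants$alt, c("G", "T"))
  expect_equal(ds$variants$pos, c(500L, 500L))
  g <- ds$genotypes
  # father is 0/1: het for alt G, and missing for the T record (carries G)
  expect_equal(g$n_alt[g$sample == "T1p" & grepl(":G$", g$key)], 1L)
  expect_true(is.na(g$n_alt[g$sample == "T1p" & grepl(":T$", g$key)]))
  # child 1/2 involves the other alt on both split records -> missing
  expect_true(all(is.na(g$n_alt[g$sample == "T1c"])))
  # AD subsetting: mother 0/2 has alt depth 50 on the T record
  expect_equal(g$ad_alt[g$sample == "T1m" & grepl(":T$", g$key)], 50)
  # PL subsetting for the T record of the mother: entries (0/0,0/2,2/2)
  expect_equal(
    unlist(g[g$sample == "T1m" & grepl(":T$", g$key),
             c("pl0", "pl1", "pl2")], use.names = FALSE),
    c(600, 0, 650))
})

test_that("records lacking PL stay usable with missing fields and a warning", {
  body <- paste(c("1", "700", ".", "C", "T", "50", "PASS", ".",
                  "GT:AD:DP:GQ",
                  "0/1:30,30:60:80", "0/0:60,0:60:80", "0/0:60,0:60:80"),
                collapse = "\t")
  trios <- read_pedigree(write_lines_tmp(ped_lines_one_trio, ".ped"))
  expect_warning(
    ds <- read_trio_vcf(write_lines_tmp(tiny_vcf_lines(body), ".vcf"),
                        trios),
    "PL")
  expect_true(all(is.na(ds$genotypes$pl0)))
  expect_false(anyNA(ds$genotypes$gq))
  seg <- segregate_all(ds)           # hard-filter path still classifies
  expect_equal(seg$calls$class, "de_novo")
})

test_that("missing sample columns are a hard error", {
  body <- paste(c("1", "700", ".", "C", "T", "50", "PASS", ".", "GT",
                  "0/1", "0/0"), collapse = "\t")
  f <- write_lines_tmp(tiny_vcf_lines(body, samples = c("T1c", "T1p")),
                       ".vcf")
  trios <- read_pedigree(write_lines_tmp(ped_lines_one_trio, ".ped"))
  expect_error(read_trio_vcf(f, trios), "T1m")
})

test_that("annotation parsing maps effects into the closed vocabulary", {
  ann <- parse_annotations(
    "DP=5;ANN=G|missense_variant|MODERATE|SPICE1|SPICE1|transcript|tx1|protein_coding|1|c.1912T>G|p.Ser638Ala",
    "ANN")
  expect_equal(ann$consequence, "missense")
  expect_equal(ann$gene_symbol, "SPICE1")
  expect_equal(ann$hgvs_c, "c.1912T>G")

  stopg <- parse_annotations(
    "ANN=A|stop_gained|HIGH|IDO2|IDO2|transcript|tx1|protein_coding|1|c.1077T>A|p.Tyr359*",
    "ANN")
  expect_equal(stopg$consequence, "stop_gained")

  other <- parse_annotations(
    "ANN=A|intergenic_region|MODIFIER|X|X|r|r|r|1|n.1A>G|", "ANN")
  expect_equal(other$consequence, "other")

  expect_warning(
    mixed <- parse_annotations("ANN=A|bad,G|synonymous_variant|LOW|Y|Y|t|t|pc|1|c.2A>G|p.=",
                               "ANN"),
    "malformed")
  expect_equal(nrow(mixed), 1)
  expect_equal(mixed$consequence, "synonymous")

  csq <- parse_annotations(
    "CSQ=G|splice_donor_variant&intron_variant|BEGAIN|ENSG1|tx9|c.-16+1G>C|",
    "CSQ")
  expect_equal(csq$consequence, "splice_site")
  expect_equal(csq$gene_symbol, "BEGAIN")
})

test_that("QUAL converts to a chance probability as its reciprocal", {
  expect_equal(qual_to_chance_prob(1), 1.0)
  expect_lt(qual_to_chance_prob(24521), 4.2e-5)
  expect_equal(qual_to_chance_prob(24521), 1 / 24521)
  expect_equal(qual_to_chance_prob(299), 1 / 299, tolerance = 1e-12)
  expect_error(qual_to_chance_prob(0))
  expect_error(qual_to_chance_prob(-3))
})

test_that("variant tables round-trip byte-identically and handle empty call sets", {
  ds <- tiny_dataset(list(c(1L, 0L, 0L), c(2L, 1L, 1L)), maf = 0.005)
  seg <- segregate_all(ds)
  f1 <- tempfile(fileext = ".tsv")
  write_variant_table(ds, seg$calls, f1)
  tab <- read_variant_table(f1)
  expect_equal(nrow(tab), 2)
  f2 <- tempfile(fileext = ".tsv")
  readr::write_tsv(tab, f2, na = "NA")
  expect_identical(readLines(f1), readLines(f2))

  f3 <- tempfile(fileext = ".tsv")
  write_variant_table(ds, seg$calls[0, ], f3)
  expect_equal(length(readLines(f3)), 1)   # header only
})

test_that("simulated datasets round-trip read -> write -> read identically", {
  sim <- simulate_trio_dataset(sim_config(n_trios = 2, n_variants = 60,
                                          seed = 11))
  dir <- tempfile()
  p <- write_simulated_dataset(sim, dir)
  trios <- read_pedigree(p$ped)
  ds1 <- read_trio_vcf(p$vcf, trios,
                       score_table = read_score_table(p$scores))
  f2 <- tempfile(fileext = ".vcf")
  write_trio_vcf(ds1, f2)
  ds2 <- read_trio_vcf(f2, trios,
                       score_table = read_score_table(p$scores))
  expect_tibble_equal(ds1$variants, ds2$variants)
  expect_tibble_equal(ds1$genotypes, ds2$genotypes)
  expect_tibble_equal(ds1$annotations, ds2$annotations)
  # emitted positions equal the simulated VCF POS values exactly
  expect_setequal(ds1$variants$pos, sim$dataset$variants$pos)
})
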