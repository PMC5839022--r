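#' @importFrom tibble tribble
NULL

# Genotype triples (child, father, mother) realizing each fixture class.
.fixture_triples <- list(
  denovo      = c(1L, 0L, 0L),
  recessive   = c(2L, 1L, 1L),
  comphet_pat = c(1L, 1L, 0L),
  comphet_mat = c(1L, 0L, 1L),
  het_pat     = c(1L, 1L, 0L),
  het_mat     = c(1L, 0L, 1L),
  het_bi      = c(1L, 1L, 1L),
  homref      = c(0L, 0L, 0L)
)

# Build a clean (noise-free) trio_dataset from a fixture specification:
# one row per variant with carrier trios and a fixture class; non-carrier
# trios are homozygous reference. Depth defaults to 100, genotype evidence
# comes from the binomial likelihood model with no allele noise.
build_fixture_dataset <- function(spec, trios, depth_default = 100,
                                  qual_default = 10000,
                                  base_error = 1e-3) {
  spec <- spec %>%
    mutate(
      ref = if ("ref" %in% names(spec)) .data$ref else "A",
      alt = if ("alt" %in% names(spec)) .data$alt else "G",
      qual = if ("qual" %in% names(spec)) {
        ifelse(is.na(.data$qual), qual_default, .data$qual)
      } else qual_default,
      depth = if ("depth" %in% names(spec)) {
        ifelse(is.na(.data$depth), depth_default, .data$depth)
      } else depth_default,
      hgvs_c = if ("hgvs_c" %in% names(spec)) .data$hgvs_c else "",
      hgvs_p = if ("hgvs_p" %in% names(spec)) .data$hgvs_p else ""
    ) %>%
    arrange(chrom_rank(.data$chrom), .data$pos, .data$alt) %>%
    mutate(key = vkey(.data$chrom, .data$pos, .data$ref, .data$alt))
  if (anyDuplicated(spec$key)) {
    stop("duplicate fixture variant keys: ",
         paste(spec$key[duplicated(spec$key)], collapse = ", "))
  }

  # memoized evidence per (n_alt, depth)
  memo <- new.env()
  ev <- function(n_alt, dp) {
    k <- paste(n_alt, dp)
    if (is.null(memo[[k]])) {
      memo[[k]] <- geno_fields(n_alt, dp, allele_noise = FALSE,
                               base_error = base_error)
    }
    memo[[k]]
  }

  gt_rows <- vector("list", nrow(spec) * nrow(trios) * 3)
  idx <- 0
  for (i in seq_len(nrow(spec))) {
    carriers <- as.integer(strsplit(spec$carriers[i], ",",
                                    fixed = TRUE)[[1]])
    triple_c <- .fixture_triples[[spec$gclass[i]]]
    for (t in seq_len(nrow(trios))) {
      triple <- if (t %in% carriers) triple_c else c(0L, 0L, 0L)
      ids <- c(trios$child_id[t], trios$father_id[t], trios$mother_id[t])
      for (m in 1:3) {
        e <- ev(triple[m], spec$depth[i])
        idx <- idx + 1
        gt_rows[[idx]] <- tibble(
          key = spec$key[i], sample = ids[m], n_alt = triple[m],
          ad_ref = e$ad_ref, ad_alt = e$ad_alt, dp = e$dp, gq = e$gq,
          pl0 = e$pl[1], pl1 = e$pl[2], pl2 = e$pl[3])
      }
    }
  }
  genotypes <- bind_rows(gt_rows)

  variants <- spec %>%
    select("key", "chrom", "pos", "ref", "alt", "qual")
  annotations <- spec %>%
    transmute(.data$key, gene_symbol = .data$gene,
              transcript_id = paste0(.data$gene, ".t1"),
              consequence = .data$consequence, hgvs_c = .data$hgvs_c,
              hgvs_p = .data$hgvs_p, allele = .data$alt)
  scores <- spec %>%
    transmute(.data$key,
              sift = if ("sift" %in% names(spec)) .data$sift else NA_real_,
              polyphen = if ("polyphen" %in% names(spec)) .data$polyphen
                         else NA_real_,
              cadd_phred = NA_real_, sift_rank = NA_real_,
              polyphen_rank = NA_real_, cadd_rank = NA_real_,
              maf = if ("maf" %in% names(spec)) .data$maf else NA_real_)
  trio_dataset(variants, genotypes, annotations, scores, trios)
}

# Synthetic score pair for fixture variants whose individual scores were
# not printed: clearly inside / outside the pathogenicity thresholds.
syn_scores <- function(pathogenic) {
  if (pathogenic) c(sift = 0.01, polyphen = 0.95) else
    c(sift = 0.4, polyphen = 0.1)
}

# The six de novo variants of the published de novo table, plus
# deterministic inherited decoys (synthetic positions).
denovo_fixture_spec <- function() {
  printed <- tribble(
    ~gene, ~carriers, ~chrom, ~pos, ~qual, ~depth, ~consequence,
    ~hgvs_c, ~hgvs_p, ~sift, ~polyphen, ~maf,
    "IGSF3", "1", "1", 117122285L, 14580, 191L, "inframe_insertion",
    "c.3122_3123insGGA", "p.Asp1040_Asp1041insGlu", NA, NA, 0.25,
    "SPICE1", "1", "3", 113172543L, 3572, 291L, "missense",
    "c.1912T>G", "p.Ser638Ala", NA, NA, NA,
    "ZNF717", "2", "3", 75781257L, 106499, 580L, "missense",
    "c.293A>C", "p.Gln98Pro", 0.06, 0, NA,
    "CTNND2", "2", "5", 10981914L, 299, 111L, "missense",
    "c.3388G>A", "p.Ala1130Thr", NA, NA, NA,
    "NPHS2", "3", "1", 179526340L, 6106, 530L, "missense",
    "c.560T>C", "p.Met187Thr", NA, NA, NA,
    "PRSS55", "3", "8", 10390473L, 3426, 172L, "missense",
    "c.656G>C", "p.Trp219Ser", NA, NA, NA
  ) %>%
    mutate(gclass = "denovo",
           ref = "A",
           alt = ifelse(.data$consequence == "inframe_insertion", "AGGA",
                        "G"))
  decoys <- tibble(
    gene = paste0("DEC", 1:6),
    carriers = as.character(rep(1:3, each = 2)),
    chrom = "2",
    pos = 10000001L + 1000L * (0:5),
    qual = NA_real_, depth = NA_integer_,
    consequence = "missense", hgvs_c = "", hgvs_p = "",
    sift = 0.5, polyphen = 0.1, maf = 0.2,
    gclass = rep(c("het_pat", "het_bi"), 3),
    ref = "A", alt = "G"
  )
  bind_rows(printed, decoys)
}

# The nine rare (MAF < 0.01 or unobserved) single-trio recessive variants
# of the published rare-recessive table, plus two common recessive decoys
# carrying the common-variant frequencies printed in the recurrence table
# (decoy placement synthetic).
rare_recessive_fixture_spec <- function() {
  printed <- tribble(
    ~gene, ~carriers, ~chrom, ~pos, ~qual, ~depth, ~consequence,
    ~sift, ~polyphen, ~maf,
    "ZNF717", "1", "3", 75787726L, 221913, 1345L, "missense", 0.14, 0.689, NA,
    "WNT2", "1", "7", 116963030L, 7083, 305L, "missense", 0.39, 0.063, 0.0011,
    "COG6", "1", "13", 40254100L, 4954, 228L, "frameshift", NA, NA, NA,
    "BEGAIN", "1", "14", 101036074L, 20030, 273L, "splice_site", NA, NA, NA,
    "NDUFV3", "1", "21", 44317156L, 8515, 341L, "missense", 0.01, 0.927, 0.0051,
    "SHROOM1", "2", "5", 132161699L, 13112, 130L, "missense", 0.02, 0.274, 0.0065,
    "FMNL1", "2", "17", 43320554L, 7318, 194L, "missense", 0.12, 1, 0.0019,
    "DCP1B", "3", "12", 2062323L, 65685, 295L, "inframe_insertion", NA, NA, 0.00784,
    "CHRNA3", "3", "15", 78913067L, 27072, 105L, "inframe_deletion", NA, NA, 0.00138
  )
  decoys <- tribble(
    ~gene, ~carriers, ~chrom, ~pos, ~qual, ~depth, ~consequence,
    ~sift, ~polyphen, ~maf,
    "Sec16A", "1", "9", 139368953L, 28526, 602L, "missense", 0.14, 0.689, 0.21,
    "AP5B1", "3", "11", 65547333L, 15898, 187L, "missense", 0, 0.999, 0.29
  )
  bind_rows(printed, decoys) %>%
    mutate(gclass = "recessive", hgvs_c = "", hgvs_p = "",
           ref = "A",
           alt = case_when(.data$consequence == "inframe_insertion" ~ "AGCA",
                           TRUE ~ "G"),
           ref = ifelse(.data$consequence %in%
                          c("inframe_deletion", "frameshift"), "ACTG",
                        .data$ref),
           alt = ifelse(.data$consequence %in%
                          c("inframe_deletion", "frameshift"), "A",
                        .data$alt))
}

# The 79 recurrent variants of the published cross-trio gene lists:
# category A (identical recessive site in >= 2 trios), category B
# (recessive in the same gene, different positions) and category C
# (compound heterozygous in >= 2 trios). Scores and positions are the
# printed ones where the paper prints them; the remainder are synthetic,
# with pathogenic/benign synthetic scores allocated so the fixture carries
# the published pathogenic fraction (58 of 79).
recurrence_fixture_spec <- function() {
  pp <- function(s, p) list(sift = s, polyphen = p)
  # category A: gene, carrier trios, chrom, pos, scores (NA = synthetic),
  # synthetic pathogenicity, maf
  a <- tribble(
    ~gene, ~carriers, ~chrom, ~pos, ~sift, ~polyphen, ~syn_path, ~maf,
    "Sec16A",  "1,2",   "9", 139368953L, 0.14, 0.689, NA,    0.21,
    "ADGRV1",  "1,2",   "5",  90006001L, NA,   NA,    FALSE, 0.10,
    "RHBDL2",  "1,3",   "1",  39351001L, NA,   NA,    TRUE,  0.10,
    "ZNF804A", "1,3",   "2", 185463001L, NA,   NA,    TRUE,  0.10,
    "AP5B1",   "1,3",  "11",  65547333L, 0,    0.999, NA,    0.29,
    "TYR",     "1,3",  "11",  88911001L, NA,   NA,    FALSE, 0.10,
    "CPAMD8",  "1,3",  "19",  17114001L, NA,   NA,    TRUE,  0.10,
    "PRSS48",  "2,3",   "4", 152199001L, NA,   NA,    TRUE,  0.10,
    "OR11G2", "1,2,3", "14",  20249001L, NA,   NA,    TRUE,  0.10
  ) %>%
    mutate(category = "A", gclass = "recessive", consequence = "missense")

  b <- tribble(
    ~gene, ~carriers, ~chrom, ~pos, ~sift, ~polyphen, ~syn_path, ~maf,
    "ASPN",    "1",  "9",  95218001L, NA,   NA,    TRUE,  0.10,
    "ASPN",    "2",  "9",  95219001L, NA,   NA,    FALSE, 0.10,
    "WFDC3",   "1", "20",  44330001L, NA,   NA,    FALSE, 0.10,
    "WFDC3",   "2", "20",  44331001L, NA,   NA,    TRUE,  0.10,
    "CCT6B",   "1", "17",  33281001L, NA,   NA,    TRUE,  0.10,
    "CCT6B",   "2", "17",  33282001L, NA,   NA,    FALSE, 0.10,
    "OBSCN",   "1",  "1", 228505204L, 0,    0.91,  NA,    0.26,
    "OBSCN",   "3",  "1", 228494790L, 0.01, 0.939, NA,    0.41,
    "SLC16A8", "1", "22",  38476001L, NA,   NA,    TRUE,  0.10,
    "SLC16A8", "3", "22",  38477001L, NA,   NA,    FALSE, 0.10,
    "AFAP1",   "2",  "4",   7941001L, NA,   NA,    FALSE, 0.10,
    "AFAP1",   "3",  "4",   7942001L, NA,   NA,    TRUE,  0.10,
    "HSD17B4", "2",  "5", 118788001L, NA,   NA,    TRUE,  0.10,
    "HSD17B4", "3",  "5", 118789001L, NA,   NA,    TRUE,  0.10,
    "DNAH11",  "2",  "7",  21630001L, NA,   NA,    TRUE,  0.10,
    "DNAH11",  "3",  "7",  21631001L, NA,   NA,    TRUE,  0.10,
    "CNGB1",   "2", "16",  57916001L, NA,   NA,    TRUE,  0.10,
    "CNGB1",   "3", "16",  57917001L, NA,   NA,    FALSE, 0.10,
    "MARCH10", "2", "17",  60770001L, NA,   NA,    TRUE,  0.10,
    "MARCH10", "3", "17",  60771001L, NA,   NA,    TRUE,  0.10,
    "RHBG",    "1",  "1", 156361001L, NA,   NA,    TRUE,  0.10,
    "RHBG",    "2",  "1", 156362001L, NA,   NA,    TRUE,  0.10,
    "RHBG",    "3",  "1", 156363001L, NA,   NA,    TRUE,  0.10,
    "KNL1",    "1", "15",  40916237L, 0.05, 0.058, NA,    0.32,
    "KNL1",    "2", "15",  40915190L, 1,    0,     NA,    0.24,
    "KNL1",    "3", "15",  40914177L, 0.01, 0.006, NA,    0.39
  ) %>%
    mutate(category = "B", gclass = "recessive", consequence = "missense")

  c_ <- tribble(
    ~gene, ~carriers, ~side, ~chrom, ~pos, ~sift, ~polyphen, ~syn_path, ~maf,
    "CMYA5",   "1", "pat",  "5",  79026001L, NA,   NA,    TRUE,  0.10,
    "CMYA5",   "1", "mat",  "5",  79027001L, NA,   NA,    TRUE,  0.10,
    "CMYA5",   "2", "pat",  "5",  79028001L, NA,   NA,    TRUE,  0.10,
    "CMYA5",   "2", "mat",  "5",  79029001L, NA,   NA,    FALSE, 0.10,
    "PCDHB16", "1", "pat",  "5", 140556001L, NA,   NA,    TRUE,  0.10,
    "PCDHB16", "1", "mat",  "5", 140557001L, NA,   NA,    FALSE, 0.10,
    "PCDHB16", "2", "pat",  "5", 140558001L, NA,   NA,    TRUE,  0.10,
    "PCDHB16", "2", "mat",  "5", 140559001L, NA,   NA,    TRUE,  0.10,
    "RREB1",   "1", "pat",  "6",   7231843L, 0,    0.999, NA,    0.11,
    "RREB1",   "1", "mat",  "6",   7246998L, 0.12, 0,     NA,    0.27,
    "RREB1",   "2", "pat",  "6",   7230680L, 0.06, 0.156, NA,    0.44,
    "RREB1",   "2", "mat",  "6",   7247344L, 0.01, 0.025, NA,    0.14,
    "AIM1L",   "1", "pat",  "1",  26680001L, NA,   NA,    TRUE,  0.10,
    "AIM1L",   "1", "mat",  "1",  26681001L, NA,   NA,    TRUE,  0.10,
    "AIM1L",   "3", "pat",  "1",  26682001L, NA,   NA,    TRUE,  0.10,
    "AIM1L",   "3", "mat",  "1",  26683001L, NA,   NA,    FALSE, 0.10,
    "IDO2",    "1", "pat",  "8",  39862881L, 0,    1,     NA,    0.48,
    "IDO2",    "1", "mat",  "8",  39873053L, 0.57, 0.024, NA,    0.06,
    "IDO2",    "3", "pat",  "8",  39872935L, NA,   NA,    NA,    0.226,
    "IDO2",    "3", "mat",  "8",  39862893L, 0.02, 0.444, NA,    0.02,
    "KIR3DL1", "1", "pat", "19",  55315001L, NA,   NA,    TRUE,  0.10,
    "KIR3DL1", "1", "mat", "19",  55316001L, NA,   NA,    FALSE, 0.10,
    "KIR3DL1", "3", "pat", "19",  55317001L, NA,   NA,    TRUE,  0.10,
    "KIR3DL1", "3", "mat", "19",  55318001L, NA,   NA,    TRUE,  0.10,
    "TDRD5",   "2", "pat",  "1", 179560001L, NA,   NA,    TRUE,  0.10,
    "TDRD5",   "2", "mat",  "1", 179561001L, NA,   NA,    FALSE, 0.10,
    "TDRD5",   "3", "pat",  "1", 179562001L, NA,   NA,    TRUE,  0.10,
    "TDRD5",   "3", "mat",  "1", 179563001L, NA,   NA,    TRUE,  0.10,
    "DNAH11",  "2", "pat",  "7",  21893993L, 0.02, 0.611, NA,    0.43,
    "DNAH11",  "2", "mat",  "7",  21584693L, 0,    0.601, NA,    0.012,
    "DNAH11",  "3", "pat",  "7",  21628242L, 0.67, 0.02,  NA,    0.13,
    "DNAH11",  "3", "mat",  "7",  21678643L, 0,    0.783, NA,    0.045,
    "PIEZO1",  "2", "pat", "16",  88716001L, NA,   NA,    TRUE,  0.10,
    "PIEZO1",  "2", "mat", "16",  88717001L, NA,   NA,    TRUE,  0.10,
    "PIEZO1",  "3", "pat", "16",  88718001L, NA,   NA,    TRUE,  0.10,
    "PIEZO1",  "3", "mat", "16",  88719001L, NA,   NA,    FALSE, 0.10,
    "FCGBP",   "2", "pat", "19",  40353001L, NA,   NA,    TRUE,  0.10,
    "FCGBP",   "2", "mat", "19",  40354001L, NA,   NA,    FALSE, 0.10,
    "FCGBP",   "3", "pat", "19",  40355001L, NA,   NA,    TRUE,  0.10,
    "FCGBP",   "3", "mat", "19",  40356001L, NA,   NA,    TRUE,  0.10,
    "PCNT",    "2", "pat", "21",  47744001L, NA,   NA,    TRUE,  0.10,
    "PCNT",    "2", "mat", "21",  47745001L, NA,   NA,    TRUE,  0.10,
    "PCNT",    "3", "pat", "21",  47746001L, NA,   NA,    TRUE,  0.10,
    "PCNT",    "3", "mat", "21",  47747001L, NA,   NA,    FALSE, 0.10
  ) %>%
    mutate(category = "C",
           gclass = ifelse(.data$side == "pat", "comphet_pat",
                           "comphet_mat"),
           # the published stop-gained truncation in IDO2 (trio 3 paternal)
           consequence = ifelse(.data$gene == "IDO2" &
                                  .data$carriers == "3" &
                                  .data$side == "pat", "stop_gained",
                                "missense"))

  spec <- bind_rows(a, b, c_) %>%
    mutate(
      sift = ifelse(is.na(.data$sift) & !is.na(.data$syn_path),
                    ifelse(.data$syn_path, syn_scores(TRUE)[["sift"]],
                           syn_scores(FALSE)[["sift"]]), .data$sift),
      polyphen = ifelse(is.na(.data$polyphen) & !is.na(.data$syn_path),
                        ifelse(.data$syn_path,
                               syn_scores(TRUE)[["polyphen"]],
                               syn_scores(FALSE)[["polyphen"]]),
                        .data$polyphen),
      source = ifelse(is.na(.data$syn_path), "printed", "synthetic"),
      hgvs_c = "", hgvs_p = "", ref = "A", alt = "G"
    )
  spec
}

# Per-trio consequence compositions of the published inherited-recessive
# tallies. The second trio's printed per-category numbers sum to 424 while
# its stated total is 435; the fixture follows the per-category numbers and
# the manifest records both.
consequence_mixes <- function() {
  list(
    trio1 = c(missense = 404, frameshift = 3, inframe_insertion = 6,
              splice_site = 14, start_lost = 2, stop_lost = 2),
    trio2 = c(missense = 409, stop_gained = 1, frameshift = 5,
              inframe_insertion = 4, inframe_deletion = 3, stop_lost = 2),
    trio3 = c(missense = 478, stop_gained = 4, frameshift = 8,
              inframe_insertion = 6, inframe_deletion = 6,
              splice_site = 12, stop_lost = 1)
  )
}

consequence_fixture_spec <- function() {
  mixes <- consequence_mixes()
  rows <- lapply(seq_along(mixes), function(t) {
    mix <- mixes[[t]]
    cons <- rep(names(mix), mix)
    n <- length(cons)
    tibble(
      gene = sprintf("CQ%d_%04d", t, seq_len(n)),
      carriers = as.character(t),
      chrom = as.character(t),
      pos = 1000001L + 100L * seq_len(n),
      consequence = cons, sift = NA_real_, polyphen = NA_real_,
      maf = 0.3, gclass = "recessive"
    )
  })
  bind_rows(rows) %>% mutate(hgvs_c = "", hgvs_p = "", ref = "A",
                             alt = "G")
}

#' Write the paper-table fixtures
#'
#' Emits deterministic fixture datasets encoding the published variant
#' tables and cross-trio gene lists: the six de novo variants (plus
#' inherited decoys), the nine rare single-trio recessives (plus two
#' common-variant decoys), the 79 recurrent variants of the three
#' recurrence categories, and per-trio consequence mixes. Each fixture is a
#' VCF + score table; a shared PED file and a JSON manifest of expected
#' counts accompany them. Positions, alleles and scores not printed in the
#' source tables are synthetic and deterministic.
#'
#' @param outdir Output directory (created if needed).
#' @return List with `paths` (named file paths) and `manifest` (expected
#'   counts), invisibly.
#' @export
make_paper_fixtures <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  trios <- default_trios(3)
  p <- function(...) file.path(outdir, paste0(...))

  write_fixture <- function(spec, name) {
    ds <- build_fixture_dataset(spec, trios)
    write_trio_vcf(ds, p(name, ".vcf"))
    write_score_table(ds, p(name, "_scores.tsv"))
    ds
  }
  write_pedigree(trios, p("fixtures", ".ped"))
  ds_dn <- write_fixture(denovo_fixture_spec(), "denovo")
  ds_rr <- write_fixture(rare_recessive_fixture_spec(), "rare_recessive")
  rec_spec <- recurrence_fixture_spec()
  ds_rc <- write_fixture(rec_spec, "recurrence")
  ds_cq <- write_fixture(consequence_fixture_spec(), "consequence")

  mixes <- consequence_mixes()
  manifest <- list(
    denovo_total = 6, denovo_per_trio = list(FAM1 = 2, FAM2 = 2, FAM3 = 2),
    rare_single_trio = 9,
    recurrence = list(a_variants = 9, a_genes = 9, b_genes = 12,
                      b_variants = 26, c_genes = 11, c_variants = 44,
                      total_variants = 79, flagged = 58,
                      flagged_percent = 73.4),
    consequence = list(
      trio1 = c(as.list(mixes$trio1), total = sum(mixes$trio1)),
      trio2 = c(as.list(mixes$trio2), category_sum = sum(mixes$trio2),
                stated_total = 435),
      trio3 = c(as.list(mixes$trio3), total = sum(mixes$trio3))
    )
  )
  jsonlite::write_json(manifest, p("manifest", ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    paths = list(
      ped = p("fixtures", ".ped"),
      denovo_vcf = p("denovo", ".vcf"),
      denovo_scores = p("denovo", "_scores.tsv"),
      rare_recessive_vcf = p("rare_recessive", ".vcf"),
      rare_recessive_scores = p("rare_recessive", "_scores.tsv"),
      recurrence_vcf = p("recurrence", ".vcf"),
      recurrence_scores = p("recurrence", "_scores.tsv"),
      consequence_vcf = p("consequence", ".vcf"),
      consequence_scores = p("consequence", "_scores.tsv"),
      manifest = p("manifest", ".json")),
    manifest = manifest))
}
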