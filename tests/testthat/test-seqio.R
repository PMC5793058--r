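test_that("FASTA write -> read round trip is the identity on id and residues", {
  set.seed(101)
  seqs <- c(rec_one = random_aa(150), rec_two = random_aa(73))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path, width = 60)
  back <- read_fasta(path)
  expect_length(back, 2L)
  expect_equal(vapply(back, `[[`, "", "id"), unname(names(seqs)))
  expect_equal(vapply(back, `[[`, "", "residues"), unname(seqs))
  expect_true(all(vapply(back, `[[`, "", "moltype") == "protein"))
})

test_that("FASTA reader rejects degenerate files with line diagnostics", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(read_fasta(empty), "empty file", class = "coralox_format_error")

  headless <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">x"), headless)
  expect_error(read_fasta(headless), "line 1", class = "coralox_format_error")

  noseq <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV", ">b"), noseq)
  expect_error(read_fasta(noseq), "no sequence lines",
               class = "coralox_format_error")

  illegal <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV1"), illegal)
  expect_error(read_fasta(illegal), "illegal", class = "coralox_format_error")
})

write_gb_fixture <- function(path, id, seq, cds = NULL, protein = FALSE,
                             origin = TRUE) {
  unit <- if (protein) "aa" else "bp"
  lines <- c(
    sprintf("LOCUS       %s %d %s    linear   INV 01-JAN-2000", id,
            nchar(seq), unit),
    "DEFINITION  synthetic fixture record.",
    sprintf("VERSION     %s", id),
    "FEATURES             Location/Qualifiers")
  if (!is.null(cds)) lines <- c(lines, sprintf("     CDS             %s", cds))
  if (origin) {
    lines <- c(lines, "ORIGIN")
    starts <- seq(1, nchar(seq), by = 60)
    lines <- c(lines, vapply(starts, function(s)
      sprintf("%9d %s", s, tolower(substr(seq, s, min(s + 59, nchar(seq))))),
      character(1)))
  }
  writeLines(c(lines, "//"), path)
  path
}

test_that("GenBank parsing extracts sequence, id, and CDS spans", {
  set.seed(7)
  nt <- random_nt(120)
  path <- withr::local_tempfile(fileext = ".gb")
  write_gb_fixture(path, "SYNTH001.1", nt, cds = "1..120")
  rec <- read_genbank(path)[[1]]
  expect_equal(rec$id, "SYNTH001.1")
  expect_equal(rec$moltype, "nucleotide")
  expect_equal(rec$residues, nt)
  expect_equal(rec$cds_features$start, 1L)
  expect_equal(rec$cds_features$end, 120L)
  expect_equal(rec$cds_features$strand, "+")

  # GenPept: protein moltype, no CDS features
  aa <- random_aa(80)
  p2 <- withr::local_tempfile(fileext = ".gp")
  write_gb_fixture(p2, "SYNTHP01.1", aa, protein = TRUE)
  rec2 <- read_genbank(p2)[[1]]
  expect_equal(rec2$moltype, "protein")
  expect_null(rec2$cds_features)
})

test_that("GenBank records without ORIGIN fail as format errors", {
  path <- withr::local_tempfile(fileext = ".gb")
  write_gb_fixture(path, "SYNTH002.1", random_nt(30), origin = FALSE)
  expect_error(read_genbank(path), "ORIGIN", class = "coralox_format_error")
})

test_that("annotated CDS translation yields L residues from L codons plus stop", {
  set.seed(11)
  aa <- random_aa(40)
  codon_for <- function(x) {
    code <- Biostrings::GENETIC_CODE
    names(code)[match(x, code)]
  }
  nt <- paste0(paste(vapply(strsplit(aa, "")[[1]], codon_for, ""),
                     collapse = ""), "TAA")
  rec <- seq_record("cds_rec", nt, moltype = "nucleotide",
                    cds_features = data.frame(start = 1L, end = nchar(nt),
                                              strand = "+"))
  out <- to_protein(rec, min_aa = 10)
  expect_length(out, 1L)
  expect_equal(out[[1]]$provenance, "annotated_cds")
  expect_equal(out[[1]]$residues, aa)
})

test_that("protein records pass through as identical as_is candidates", {
  rec <- seq_record("prot", random_aa(120), moltype = "protein")
  out <- to_protein(rec)
  expect_length(out, 1L)
  expect_equal(out[[1]]$provenance, "as_is")
  expect_equal(out[[1]]$residues, rec$residues)
})

test_that("longest-ORF translation matches exhaustive six-frame enumeration", {
  set.seed(23)
  for (k in 1:25) {
    nt <- random_nt(sample(90:300, 1))
    rec <- seq_record(sprintf("orf_%02d", k), nt, moltype = "nucleotide")
    got <- to_protein(rec, min_aa = 10)
    want <- oracle_longest_orf(nt, min_aa = 10)
    if (is.null(want)) {
      expect_length(got, 0L)
    } else {
      expect_length(got, 1L)
      expect_equal(got[[1]]$residues, want$protein)
      expect_equal(got[[1]]$frame, want$frame)
    }
  }
})

test_that("a planted ORF inside random sequence is recovered with its frame", {
  set.seed(31)
  core <- random_aa(60)
  core <- gsub("M", "L", core)   # avoid internal upstream starts
  codon_for <- function(x) {
    code <- Biostrings::GENETIC_CODE
    names(code)[match(x, code)]
  }
  orf_nt <- paste0("ATG",
                   paste(vapply(strsplit(core, "")[[1]], codon_for, ""),
                         collapse = ""), "TGA")
  # plant on the minus strand inside random flanks
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  nt <- paste0(random_nt(17), rc(orf_nt), random_nt(20))
  got <- to_protein(seq_record("planted", nt, moltype = "nucleotide"),
                    min_aa = 30)
  want <- oracle_longest_orf(nt, min_aa = 30)
  expect_length(got, 1L)
  expect_equal(got[[1]]$residues, want$protein)
  expect_lt(got[[1]]$frame, 0L)
  expect_true(startsWith(got[[1]]$residues, "M"))
})

test_that("domain extraction respects bounds and concatenation", {
  p <- protein_candidate("fus", random_aa(1066), "as_is")
  aos <- extract_domain(p, 1, 373)
  lox <- extract_domain(p, 374, 1066)
  expect_equal(nchar(aos), 373L)
  expect_equal(nchar(lox), 693L)
  expect_equal(paste0(aos, lox), p$residues)
  expect_error(extract_domain(p, 1, 2000), class = "coralox_bounds_error")
  expect_error(extract_domain(p, 0, 10), class = "coralox_bounds_error")
})
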