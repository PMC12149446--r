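test_that("a hand-written PDB fixture round-trips through the data model", {
  tmp <- write_tiny_pdb(tempfile(fileext = ".pdb"))
  m <- read_structure(tmp)
  expect_length(m$chains, 1)
  ch <- m$chains[["A"]]
  expect_equal(sort(unique(ch$atoms$auth_seq)), 1:3)
  expect_equal(nrow(ch$atoms), 12)
  expect_equal(ch$atoms$x[ch$atoms$name == "CA" & ch$atoms$auth_seq == 2], 4.8)

  # write -> read preserves coordinates to PDB precision
  out <- tempfile(fileext = ".pdb")
  write_pdb(m, out)
  m2 <- read_structure(out)
  expect_equal(m2$chains[["A"]]$atoms$x, ch$atoms$x, tolerance = 1e-3)
  expect_equal(m2$chains[["A"]]$atoms$z, ch$atoms$z, tolerance = 1e-3)
})

test_that("the same content read as PDB and mmCIF gives identical coordinates", {
  pdb <- read_structure(write_tiny_pdb(tempfile(fileext = ".pdb")))
  cif <- suppressWarnings(
    read_structure(write_tiny_cif(tempfile(fileext = ".cif"))))
  a <- pdb$chains[["A"]]$atoms
  b <- cif$chains[["A"]]$atoms
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$x, b$x)
  expect_equal(a$y, b$y)
  expect_equal(a$z, b$z)
  expect_equal(a$name, b$name)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  m <- read_structure(write_tiny_pdb(tempfile(fileext = ".pdb"),
                                     altloc = TRUE))
  cb <- m$chains[["A"]]$atoms
  cb <- cb[cb$name == "CB", , drop = FALSE]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$altloc, "A")
  expect_equal(cb$occ, 0.7)
})

test_that("select_domain honors spans, modes and their nesting", {
  m <- read_structure(write_tiny_pdb(tempfile(fileext = ".pdb")))
  ch <- m$chains[["A"]]
  span12 <- domain_span("DBD", 1, 2)
  expect_equal(nrow(select_domain(ch, span12, "ca")), 2)
  expect_equal(nrow(select_domain(ch, span12, "backbone")), 8)
  expect_error(select_domain(ch, domain_span("LBD", 900, 950)),
               "empty selection")
  # atom-set nesting: all >= backbone >= ca per residue
  all_a <- select_domain(ch, span12, "all")
  bb <- select_domain(ch, span12, "backbone")
  ca <- select_domain(ch, span12, "ca")
  key <- function(df) paste(df$auth_seq, df$name)
  expect_true(all(key(bb) %in% key(all_a)))
  expect_true(all(key(ca) %in% key(bb)))
})

test_that("pLDDT tracks scale by 1/100 and reject out-of-range or rescaled input", {
  h <- make_ideal_helix(6)
  at <- h$atoms
  at$b[at$name == "CA"] <- c(91.2, 100, 75, 60.5, 88, 99)
  at$b[at$name != "CA"] <- 50
  ch <- chain_model("A", at, "predicted")
  m <- structure_model("AF-TEST", list(ch))
  tr <- load_plddt_track(m, "A")
  expect_equal(unname(tr$values[1]), 0.912)
  expect_equal(unname(tr$values[2]), 1.0)

  at_bad <- at
  at_bad$b[at_bad$name == "CA"][1] <- 120
  m_bad <- structure_model("AF-BAD", list(chain_model("A", at_bad, "predicted")))
  expect_error(load_plddt_track(m_bad, "A"), "outside \\[0,100\\]")

  at$b <- at$b / 100    # already-scaled values must be rejected, not rescaled
  m_scaled <- structure_model("AF-S", list(chain_model("A", at, "predicted")))
  expect_error(load_plddt_track(m_scaled, "A"), "already")

  expect_error(load_plddt_track(m, "Z"), "not found")
  m_exp <- structure_model("X", list(chain_model("A", h$atoms, "experimental")))
  expect_error(load_plddt_track(m_exp, "A"), "predicted")
})

test_that("validation-report RSCC parsing keys by author numbering", {
  xml <- write_tiny_validation_xml(tempfile(fileext = ".xml"))
  tr <- read_validation_rscc(xml, "A")
  expect_equal(unname(tr$values), c(0.95, 0.80, -0.10))
  expect_equal(names(tr$values), c("1", "2", "3"))

  expect_error(read_validation_rscc(xml, "B"), "no RSCC data for chain")

  dup <- write_tiny_validation_xml(tempfile(fileext = ".xml"),
                                   duplicate = TRUE)
  expect_error(read_validation_rscc(dup, "A"), "duplicate RSCC entry")

  empty <- tempfile(fileext = ".xml")
  writeLines(c("<wwPDB_validation_information><Entry>",
               "</Entry></wwPDB_validation_information>"), empty)
  expect_error(read_validation_rscc(empty, "A"), "no RSCC data")
})
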