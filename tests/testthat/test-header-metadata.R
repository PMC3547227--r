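test_that("R-AXIS header fixture parses to the documented field values", {
  md <- parseRaxisHeader(raxisHeaderPath())
  expect_s4_class(md, "ImageMetadata")
  expect_identical(headerDialect(md), "raxis")
  expect_identical(scanAxis(md), "phi")
  expect_equal(rotationPerFrame(md), 1.0)
  expect_equal(startAngles(md)[["phi"]], 0)
  expect_equal(startAngles(md)[["omega"]], 0)
  expect_equal(startAngles(md)[["chi"]], 0)
  expect_equal(startAngles(md)[["theta"]], 0)
  expect_identical(md@nFast, 3000L)
  expect_identical(md@nSlow, 3000L)
  expect_equal(md@pixelSize, 100)
  expect_equal(unname(beamCenter(md)), c(1500, 1500))
  ## no gain in the dialect: default 1.0 plus a ledger entry
  expect_equal(gain(md), 1.0)
  expect_true("gain" %in% missingFields(md))
  ## empty a4cSpindle
  expect_identical(spindleSense(md), "unknown")
  expect_true("spindle orientation" %in% missingFields(md))
  expect_identical(md@overflowScheme, "raxis_scaled")
  expect_equal(md@overflowRatio, 8)
})

test_that("Bruker header fixture parses to the documented field values", {
  md <- parseBrukerHeader(brukerHeaderPath())
  expect_identical(headerDialect(md), "bruker")
  ## ANGLES maps in order to 2theta, omega, phi, chi
  expect_equal(startAngles(md),
               c(two_theta = 0, omega = 358.75, phi = 0, chi = 0))
  ## AXIS: 3 -> phi scan
  expect_identical(scanAxis(md), "phi")
  ## gain is the first CCDPARM numeric
  expect_equal(gain(md), 3.83)
  expect_identical(md@nFast, 1024L)
  expect_identical(md@nSlow, 1024L)
  expect_equal(md@pixelSize, 89.99)
  expect_equal(md@baselineOffset, 32)
  expect_equal(rotationPerFrame(md), 0.5)
  expect_identical(md@overflowScheme, "bruker_table")
  refs <- correctionRefs(md)
  expect_identical(unname(refs["flood_field"]), "0138_1024_180s._fl")
  expect_identical(unname(refs["distortion"]), "0138_1024_180s._ix")
  expect_identical(unname(refs["dark"]), "0138_01024_00010._dk")
})

test_that("parsers fail hard on malformed or absent mandatory fields", {
  bruker <- readLines(brukerHeaderPath())
  ## missing NPIXELB: pixel depth unrecoverable
  expect_error(parseBrukerHeader(bruker[!grepl("^NPIXELB", bruker)]),
               "NPIXELB")
  ## AXIS outside the documented set
  bad <- sub("^AXIS   : 3", "AXIS   : 7", bruker)
  expect_error(parseBrukerHeader(bad), "AXIS")
  ## malformed numeric names the key
  bad2 <- sub("^ANGLES : 0.0 358.75 0.0 0.0", "ANGLES : 0.0 x 0.0 0.0", bruker)
  expect_error(parseBrukerHeader(bad2), "ANGLES")

  raxis <- readLines(raxisHeaderPath())
  expect_error(parseRaxisHeader(raxis[!grepl("^nFast", raxis)]), "nFast")
  expect_error(parseRaxisHeader(sub("a3fPhi         0.0 0.0 1.0",
                                    "a3fPhi         0.0 0.0 oops", raxis,
                                    fixed = TRUE)),
               "a3fPhi")
})

test_that("metadata audit reports the known gaps and is monotone", {
  mdR <- parseRaxisHeader(raxisHeaderPath())
  fr <- auditMetadata(mdR)
  expect_true(all(c("spindle orientation", "fast/slow convention",
                    "gain", "goniometer axis layout") %in% fr$field))

  mdB <- parseBrukerHeader(brukerHeaderPath())
  fb <- auditMetadata(mdB)
  ## correction provenance all present in the fixture
  expect_false(any(grepl("provenance", fb$field)))

  ## a fully specified header description audits clean
  mdFull <- mdB
  mdFull@spindleSense <- "ccw"
  mdFull@missingFields <- character(0)
  expect_identical(nrow(auditMetadata(mdFull)), 0L)

  ## removing a field never shrinks the findings list
  bruker <- readLines(brukerHeaderPath())
  dropOne <- function(pat) parseBrukerHeader(bruker[!grepl(pat, bruker)])
  for (pat in c("^CORRECT", "^WARFIL", "^DARK", "^CCDPARM", "^INCREME")) {
    f2 <- auditMetadata(dropOne(pat))
    expect_true(all(fb$field %in% f2$field), info = pat)
    expect_gt(nrow(f2), nrow(fb))
  }
})

test_that("pixel decoding follows the documented overflow rules", {
  mdB <- exampleImageMetadata("bruker", nFast = 4L)
  ## identity when no sentinel, baseline 0
  expect_equal(decodePixels(c(0L, 10L, 200L, 254L), mdB), c(0, 10, 200, 254))
  ## sentinel replaced by table entry, then baseline subtracted
  expect_equal(decodePixels(c(10L, 255L, 3L, 0L), mdB, overflowTable = 70000),
               c(10, 70000, 3, 0))
  mdB32 <- exampleImageMetadata("bruker", nFast = 2L, baselineOffset = 32)
  expect_equal(decodePixels(c(40L, 255L), mdB32, overflowTable = 70000),
               c(8, 70000 - 32))
  ## more sentinels than table entries
  expect_error(decodePixels(c(255L, 255L, 1L, 2L), mdB, overflowTable = 1000),
               "sentinel")

  mdR <- exampleImageMetadata("raxis", nFast = 2L)
  ## stored 32768 -> 0; stored 32769 -> R = 8
  expect_equal(decodePixels(c(32768L, 32769L), mdR), c(0, 8))
  expect_equal(decodePixels(c(5L, 40000L), mdR), c(5, (40000 - 32768) * 8))
  ## raw byte input is little-endian pairs; odd byte count errors
  expect_equal(decodePixels(as.raw(c(0x01, 0x00, 0x00, 0x80)), mdR),
               c(1, 0))
  mdR3 <- exampleImageMetadata("raxis", nFast = 3L)
  expect_error(decodePixels(as.raw(c(1, 0, 2)), mdR3), "odd byte count")
})

test_that("encode/decode round-trips are identities on their domains", {
  set.seed(42)
  mdB <- exampleImageMetadata("bruker", nFast = 500L, baselineOffset = 32)
  x <- sample(0:1000000, 500, replace = TRUE)
  enc <- encodePixels(x, mdB)
  expect_false(any(enc$lossy))
  expect_equal(decodePixels(enc$raw, mdB, enc$overflowTable), as.numeric(x))

  ## all-zero array: zero buffer, empty overflow table
  md0 <- exampleImageMetadata("bruker", nFast = 8L)
  enc0 <- encodePixels(rep(0, 8), md0)
  expect_identical(enc0$raw, rep(0L, 8L))
  expect_length(enc0$overflowTable, 0L)

  mdR <- exampleImageMetadata("raxis", nFast = 500L)
  ## grid-representable values round-trip exactly
  small <- sample(0:32767, 250, replace = TRUE)
  big <- sample(0:32767, 250, replace = TRUE) * 8
  y <- c(small, big)
  encR <- encodePixels(y, mdR)
  expect_false(any(encR$lossy))
  expect_equal(decodePixels(encR$raw, mdR), as.numeric(y))

  ## off-grid value: nearest-grid encode flagged lossy
  mdR1 <- exampleImageMetadata("raxis", nFast = 1L)
  encL <- encodePixels(40001, mdR1)
  expect_true(encL$lossy[1L])
  expect_equal(decodePixels(encL$raw, mdR1), 40000)

  ## out-of-range errors
  expect_error(encodePixels((65535 - 32768) * 8 + 8, mdR1), "range")
  expect_error(encodePixels(-1, mdR1), "non-negative")
})
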