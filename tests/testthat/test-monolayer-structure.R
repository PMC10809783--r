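test_that("loadFrames reads GRO and PDB, resolves species, reports unknowns", {
  b <- buildMonolayerFrame(monolayerSpec(nLipidsPerLeaflet = 40,
                                         lcPatchFraction = 1,
                                         nChemical = 10))
  f <- withr::local_tempfile(fileext = ".gro")
  writeGRO(b$frame, f)
  fr <- loadFrames(f)[[1]]
  expect_equal(nAtoms(fr), nAtoms(b$frame))
  expect_identical(atomSpecies(fr), atomSpecies(b$frame))
  expect_lt(max(abs(atomCoords(fr) - atomCoords(b$frame))), 6e-4)
  expect_equal(boxDims(fr), boxDims(b$frame), tolerance = 1e-5)
  expect_equal(max(fr@moleculeId), max(b$frame@moleculeId))

  # multi-frame GRO: consecutive blocks come back in order
  writeGRO(list(b$frame, b$frame), f)
  expect_length(loadFrames(f), 2L)

  # multi-model PDB
  p <- withr::local_tempfile(fileext = ".pdb")
  writePDB(list(b$frame, b$frame, b$frame), p)
  frs <- loadFrames(p)
  expect_length(frs, 3L)
  expect_lt(max(abs(atomCoords(frs[[2]]) - atomCoords(b$frame))), 6e-5)

  # unknown residue without a mapping names the offender
  lines <- readLines(p)
  lines <- sub("DPPC", "XYZ ", lines, fixed = TRUE)
  writeLines(lines, p)
  expect_error(loadFrames(p), "XYZ")

  # missing box record
  writeLines(lines[!startsWith(lines, "CRYST1")], p)
  expect_error(loadFrames(p), "CRYST1")
})

test_that("assignLeaflets splits by the water midplane with an upper tie-break", {
  b <- buildMonolayerFrame(monolayerSpec(nLipidsPerLeaflet = 40,
                                         lcPatchFraction = 1))
  leaf <- assignLeaflets(b$frame)
  expect_equal(sum(leaf$leaflet == "upper"), 40)
  expect_equal(sum(leaf$leaflet == "lower"), 40)
  mid <- mean(atomCoords(b$frame)[atomSpecies(b$frame) == "WATER", 3])
  expect_true(all((leaf$headZ > mid) == (leaf$leaflet == "upper")))

  # single-leaflet frame with an explicit midplane: all upper
  keep <- b$frame@coords[, 3] > mid | b$frame@species != "WATER"
  up <- leaf$moleculeId[leaf$leaflet == "upper"]
  sel <- b$frame@moleculeId %in% up
  fr1 <- MonolayerFrame(b$frame@coords[sel, ], b$frame@atomName[sel],
                        b$frame@element[sel], b$frame@resName[sel],
                        b$frame@species[sel], b$frame@moleculeId[sel],
                        b$frame@box)
  expect_error(assignLeaflets(fr1), "midplane")
  l1 <- assignLeaflets(fr1, midplane = mid)
  expect_true(all(l1$leaflet == "upper"))

  # a head exactly at the midplane goes upper with a warning
  fr2 <- fr1
  i <- which(fr2@atomName == "P")[1]
  fr2@coords[i, 3] <- 1.5
  expect_warning(l2 <- assignLeaflets(fr2, midplane = 1.5), "midplane")
  expect_identical(l2$leaflet[l2$moleculeId == fr2@moleculeId[i]],
                   "upper")
})

test_that("areaPerLipid is box area over leaflet count, in Angstrom^2", {
  mk <- function(L, n) {
    coords <- rbind(cbind(runif(n, 0, L), runif(n, 0, L), 3),
                    c(L / 2, L / 2, 0))
    MonolayerFrame(coords, c(rep("P", n), "OW"),
                   c(rep("P", n), "O"), c(rep("DPPC", n), "SOL"),
                   c(rep("DPPC", n), "WATER"), seq_len(n + 1),
                   box = c(L, L, 6))
  }
  set.seed(1)
  expect_equal(areaPerLipid(mk(10, 100)), 100)
  f <- mk(9.05, 149)
  expect_equal(areaPerLipid(f), 9.05^2 * 100 / 149, tolerance = 1e-12)
  expect_equal(round(areaPerLipid(f), 2), 54.97)
  # doubling box x doubles APL
  f2 <- mk(10, 100); f2@box[1] <- 20
  expect_equal(areaPerLipid(f2), 200)
  expect_error(areaPerLipid(mk(10, 3), "lower"), "no lipids")
})

test_that("packingFraction is 1 on a wrapped hexagonal lattice and 0 on a sparse gas", {
  b1 <- buildMonolayerFrame(monolayerSpec(nLipidsPerLeaflet = 101,
                                          lcPatchFraction = 1,
                                          latticeSpacing = 0.48))
  pk1 <- packingFraction(b1$frame)
  expect_identical(lcFraction(pk1), 1)
  expect_gte(pk1@nEntities, 200L)

  b0 <- buildMonolayerFrame(monolayerSpec(lcPatchFraction = 0))
  pk0 <- packingFraction(b0$frame)
  expect_identical(lcFraction(pk0), 0)
  expect_true(all(pk0@clusterLabels == -1L))

  # lower leaflet mirrors the construction
  expect_identical(lcFraction(packingFraction(b1$frame, "lower")), 1)
})

test_that("packingFraction equals the brute-force DBSCAN oracle on mixed frames", {
  skip_if_not_installed("igraph")
  b <- buildMonolayerFrame(monolayerSpec(nLipidsPerLeaflet = 80,
                                         lcPatchFraction = 0.5,
                                         seed = 9))
  pk <- packingFraction(b$frame)
  xy <- cbind(pk@entityTable$x, pk@entityTable$y)
  want <- oracle_dbscan(xy, boxDims(b$frame)[1:2], 0.71, 6)
  expect_identical(canon_labels(pk@clusterLabels), canon_labels(want))
  expect_equal(lcFraction(pk), sum(want >= 0) / length(want))
})

test_that("packingFraction is invariant to rigid translation and has working flags", {
  b <- buildMonolayerFrame(monolayerSpec(nLipidsPerLeaflet = 80,
                                         lcPatchFraction = 0.5,
                                         seed = 2))
  base <- packingFraction(b$frame)
  shifted <- b$frame
  L <- boxDims(b$frame)[1]
  shifted@coords[, 1] <- (shifted@coords[, 1] + 3.7) %% L
  shifted@coords[, 2] <- (shifted@coords[, 2] + 1.3) %% L
  expect_equal(lcFraction(packingFraction(shifted)), lcFraction(base))

  # includeSelf relaxes the core rule, countBorder = FALSE drops borders
  relax <- packingFraction(b$frame, includeSelf = TRUE)
  expect_gte(lcFraction(relax), lcFraction(base))
  strict <- packingFraction(b$frame, countBorder = FALSE)
  expect_lte(lcFraction(strict), lcFraction(base))

  # too few entities: fraction 0 with a warning, not an error
  tiny <- buildMonolayerFrame(monolayerSpec(nLipidsPerLeaflet = 40,
                                            lcPatchFraction = 0,
                                            apl = 115))
  few <- tiny$frame
  keep_mol <- unique(few@moleculeId[few@species %in%
                                      c("DPPC", "WATER")])[1:3]
  sel <- few@moleculeId %in% keep_mol | few@species == "WATER"
  few2 <- MonolayerFrame(few@coords[sel, ], few@atomName[sel],
                         few@element[sel], few@resName[sel],
                         few@species[sel], few@moleculeId[sel], few@box)
  expect_warning(pk <- packingFraction(few2), "entities")
  expect_identical(lcFraction(pk), 0)
})

test_that("chainTilt measures the C1->C16 angle folded to [0, 90] degrees", {
  n <- 64L
  down <- matrix(rep(c(0, 0, -1), each = n), ncol = 3)
  expect_equal(chainTilt(chain_frame(down))@meanTilt, 0)

  th <- 25 * pi / 180
  tilted <- cbind(sin(th), 0, cos(th))[rep(1, n), ]
  tr <- chainTilt(chain_frame(tilted))
  expect_equal(tr@meanTilt, 25, tolerance = 1e-9)
  expect_identical(tr@nChains, n)

  # rigid rotation about z leaves tilt unchanged
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3)
  fr <- chain_frame(tilted)
  rot <- fr
  ctr <- colMeans(fr@coords)
  rot@coords <- sweep(sweep(fr@coords, 2, ctr) %*% R, 2, ctr, `+`)
  rot@coords[, 1] <- rot@coords[, 1] %% fr@box[1]
  rot@coords[, 2] <- rot@coords[, 2] %% fr@box[2]
  expect_equal(chainTilt(rot)@meanTilt, 25, tolerance = 1e-9)

  # missing 16th-carbon markers are a marker error
  broken <- fr
  broken@atomName[broken@atomName == "C216"][1] <- "C215"
  expect_error(chainTilt(broken), "16th")
})

test_that("hemisphere-uniform chain directions average to 1 radian of tilt", {
  set.seed(77)
  n <- 1e5
  cz <- runif(n)                 # area-uniform on the hemisphere
  ph <- runif(n, 0, 2 * pi)
  sz <- sqrt(1 - cz^2)
  dirs <- cbind(sz * cos(ph), sz * sin(ph), cz)
  tr <- chainTilt(chain_frame(dirs, box = c(400, 400, 12)))
  expect_lt(abs(tr@meanTilt - 180 / pi), 1)
})

test_that("densityProfile centers on the phosphate plane and normalizes to 1", {
  b <- buildMonolayerFrame(monolayerSpec(nLipidsPerLeaflet = 60,
                                         lcPatchFraction = 1,
                                         nChemical = 40,
                                         chemicalZOffset = 1.0))
  dp <- densityProfile(list(b$frame), list(CHEMICAL = "CHEMICAL"))
  pk <- dp@zGrid[which.max(dp@density[, "CHEMICAL"])]
  expect_lt(abs(pk - 1.0), dp@binWidth / 2 + 1e-12)
  expect_identical(max(dp@density[, "CHEMICAL"]), 1)
  # all chemicals share one z: a single occupied bin
  expect_identical(sum(dp@counts[, "CHEMICAL"] > 0), 1L)
})

test_that("densityProfile matches a histogram oracle on Gaussian placements", {
  b <- buildMonolayerFrame(monolayerSpec(nLipidsPerLeaflet = 60,
                                         lcPatchFraction = 1))
  fr <- b$frame
  set.seed(123)
  nc <- 5000L
  L <- boxDims(fr)[1]
  pz <- mean(fr@coords[fr@atomName == "P" &
                         fr@coords[, 3] > fr@box[3] / 2, 3])
  zc <- pz + rnorm(nc, 0.8, 0.2)
  add <- MonolayerFrame(
    rbind(fr@coords, cbind(runif(nc, 0, L), runif(nc, 0, L), zc)),
    c(fr@atomName, rep("CB", nc)), c(fr@element, rep("C", nc)),
    c(fr@resName, rep("CHEM", nc)), c(fr@species, rep("CHEMICAL", nc)),
    c(fr@moleculeId, max(fr@moleculeId) + seq_len(nc)), fr@box)
  dp <- densityProfile(list(add), list(CHEMICAL = "CHEMICAL"))
  # oracle: plain histogram of the same draws on the same breaks
  rel <- zc - pz
  peak <- dp@zGrid[which.max(dp@density[, "CHEMICAL"])]
  expect_lt(abs(peak - 0.8), dp@binWidth + 1e-12)
  expect_identical(max(dp@density[, "CHEMICAL"]), 1)
  expect_identical(sum(dp@counts[, "CHEMICAL"]), as.numeric(nc))
  hcounts <- tabulate(findInterval(rel, dp@zGrid - dp@binWidth / 2),
                      nbins = length(dp@zGrid))
  expect_equal(dp@counts[, "CHEMICAL"], as.numeric(hcounts),
               ignore_attr = TRUE)

  # two species offset by 0.5 nm peak 0.5 +- binWidth apart
  sp2 <- add
  sp2@species[sp2@species == "CHEMICAL"][1:2500] <- "ION"
  sp2@coords[sp2@species == "ION", 3] <-
    sp2@coords[sp2@species == "ION", 3] + 0.5
  dp2 <- densityProfile(list(sp2), list(A = "CHEMICAL", B = "ION"))
  sep <- dp2@zGrid[which.max(dp2@density[, "B"])] -
    dp2@zGrid[which.max(dp2@density[, "A"])]
  expect_lt(abs(sep - 0.5), dp2@binWidth + 1e-12)

  # an absent species is flagged, not an error
  dp3 <- densityProfile(list(add), list(PROTEIN = "PROTEIN"))
  expect_identical(dp3@emptySpecies, "PROTEIN")
  expect_true(all(dp3@density[, "PROTEIN"] == 0))
})

test_that("contactCount counts periodic heavy-atom pairs and normalizes by N_A x N_B", {
  box <- c(5, 5, 5)
  fr <- bare_frame(rbind(c(1, 1, 1), c(1, 1, 1.5)),
                   c("PROTEIN", "CHEMICAL"), box)
  expect_equal(as.numeric(contactCount(fr, "PROTEIN", "CHEMICAL")), 1)
  fr2 <- bare_frame(rbind(c(1, 1, 1), c(1, 1, 1.7)),
                    c("PROTEIN", "CHEMICAL"), box)
  expect_equal(as.numeric(contactCount(fr2, "PROTEIN", "CHEMICAL")), 0)
  # periodic image: separation 4.9 across the boundary is 0.1
  fr3 <- bare_frame(rbind(c(0.05, 1, 1), c(4.95, 1, 1)),
                    c("PROTEIN", "CHEMICAL"), box)
  expect_equal(as.numeric(contactCount(fr3, "PROTEIN", "CHEMICAL")), 1)
  # symmetry and monotonicity in the cutoff
  set.seed(8)
  pts <- matrix(runif(120 * 3, 0, 5), ncol = 3)
  frm <- bare_frame(pts, rep(c("PROTEIN", "CHEMICAL"), each = 60), box)
  ab <- as.numeric(contactCount(frm, "PROTEIN", "CHEMICAL"))
  ba <- as.numeric(contactCount(frm, "CHEMICAL", "PROTEIN"))
  expect_identical(ab, ba)
  cuts <- c(0.3, 0.6, 0.9)
  vals <- vapply(cuts, function(ct)
    as.numeric(contactCount(frm, "PROTEIN", "CHEMICAL", ct)),
    numeric(1))
  expect_true(all(diff(vals) >= 0))
  # hydrogens are excluded; empty/overlapping groups are errors
  frh <- frm; frh@element[1:60] <- "H"
  expect_error(contactCount(frh, "PROTEIN", "CHEMICAL"), "empty")
  expect_error(contactCount(frm, "PROTEIN", c("PROTEIN", "CHEMICAL")),
               "disjoint")
})

test_that("contactCount equals the O(N^2) enumeration oracle including images", {
  set.seed(31)
  box <- c(4, 4, 4)
  pts <- matrix(runif(200 * 3, 0, 4), ncol = 3)
  fr <- bare_frame(pts, rep(c("PROTEIN", "CHEMICAL"), each = 100), box)
  got <- as.numeric(contactCount(fr, "PROTEIN", "CHEMICAL", 0.6))
  want <- oracle_contacts(pts[1:100, ], pts[101:200, ], box, 0.6)
  expect_identical(got, want)
})

test_that("contactsVsArea bins per-frame contacts by APL and flags gaps", {
  s <- simulateCompressionSeries(nFrames = 8, nChemical = 12,
                                 nProbe = 6)
  gt <- s$groundTruth
  breaks <- seq(50, 115, by = 5)
  cs <- contactsVsArea(s$frames, "PROTEIN", "CHEMICAL", breaks,
                       groupPair = c("PROTEIN", "CHEMICAL"))
  expect_s4_class(cs, "ContactSeries")
  expect_true(all(diff(cs@aplGrid) > 0))
  # closed form: binned means of the constructed per-frame values
  bin <- findInterval(gt$apl, breaks, rightmost.closed = TRUE)
  want <- tapply(gt$contacts_true, bin, mean)
  want <- want[order(as.numeric(names(want)))]
  expect_equal(cs@contacts, as.numeric(want), tolerance = 1e-12)
  # constant series comes out flat
  cs2 <- contactsVsArea(s$frames[c(3, 3, 3)], "PROTEIN", "CHEMICAL",
                        breaks)
  expect_true(all(cs2@contacts == cs2@contacts[1]))
  # bins that miss the data are flagged as out-of-range frames
  cs3 <- contactsVsArea(s$frames, "PROTEIN", "CHEMICAL", c(200, 210))
  expect_identical(cs3@nOutOfRange, length(s$frames))
})

test_that("replicaAggregate means replicas and halves their difference", {
  mk <- function(v) new("ContactSeries", aplGrid = c(60, 70, 80),
                        contacts = v, error = rep(0, 3),
                        groupPair = c("A", "B"), emptyBins = integer(),
                        nOutOfRange = 0L)
  agg <- replicaAggregate(mk(c(1, 2, 3)), mk(c(3, 2, 1)))
  expect_equal(agg@contacts, c(2, 2, 2))
  expect_equal(agg@error, c(1, 0, 1))
  same <- replicaAggregate(mk(c(1, 2, 3)), mk(c(1, 2, 3)))
  expect_true(all(same@error == 0))
  bad <- new("ContactSeries", aplGrid = c(60, 70), contacts = c(1, 2),
             error = c(0, 0), groupPair = c("A", "B"),
             emptyBins = integer(), nOutOfRange = 0L)
  expect_error(replicaAggregate(mk(c(1, 2, 3)), bad), "align")
})
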