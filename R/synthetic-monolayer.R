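## Synthetic two-leaflet monolayer frames with exact ground truth.
## Lipids are coarse marker-bearing rods (every analysis consumes only
## the marker atoms and heavy-atom positions): a phospholipid is one P
## plus two chains of C1/C10/C16 markers (CHARMM-style names
## C22/C210/C216 and C32/C310/C316); cholesterol is O3 + C14. The
## condensed (L_c) patch is a hexagonal lattice strip that wraps the
## box in x, so under the 0.71 nm / 6-neighbor DBSCAN rule every patch
## entity is core or border; disordered entities sit on a jittered
## triangular lattice with minimum spacing > 0.71 nm, so they can never
## join a cluster. The achieved entity fraction and realized chain
## tilts are recorded as the ground truth.

.CHAIN_LEN <- 1.9          # C1 -> C16 distance, nm (15 bonds)
.C10_FRAC <- 9 / 15        # C10 position along the chain
.HEAD_Z <- 1.0             # phosphate plane distance from midplane, nm
.C1_Z <- 1.2
.SPARSE_SPACING <- 0.72    # > DBSCAN eps 0.71 after jitter
.SPARSE_JITTER <- 0.003
.PATCH_GAP <- 0.8          # patch <-> disordered separation, nm

#' Specification of a synthetic monolayer frame
#'
#' Defaults follow the protein-free static systems: 149 lipids per
#' leaflet at DPPC:POPC:POPG:cholesterol molar ratios 68:20:10:2. The
#' default area per lipid (100 A^2) sits at the expanded end of the
#' 50-100 A^2 band the static systems scanned: it is the regime where a
#' disordered remainder can be placed with unambiguous (> 0.71 nm)
#' spacing.
#'
#' @param nLipidsPerLeaflet lipid count per leaflet.
#' @param compositionRatio molar ratios (DPPC, POPC, POPG, CHOL).
#' @param apl area per lipid, Angstrom^2, within [40, 120].
#' @param lcPatchFraction requested condensed entity fraction in [0, 1].
#' @param latticeSpacing condensed-lattice spacing, nm (default 0.48,
#'   a typical condensed-phase chain spacing).
#' @param tiltDeg uniform tilt of condensed-patch chains, degrees.
#' @param nChemical number of interfacial chemical particles.
#' @param chemicalZOffset chemical z offset from the upper phosphate
#'   plane, nm.
#' @param includeProtein insert a compact protein-like blob of heavy
#'   atoms in the upper leaflet.
#' @param nWaterMarkers water marker atoms locating the midplane.
#' @param seed RNG seed (disordered placement, tilts, chemical xy).
#' @return A validated `monolayerSpec` list.
#' @export
monolayerSpec <- function(nLipidsPerLeaflet = 149L,
                          compositionRatio = c(DPPC = 68, POPC = 20,
                                               POPG = 10, CHOL = 2),
                          apl = 100, lcPatchFraction = 0.5,
                          latticeSpacing = 0.48, tiltDeg = 25,
                          nChemical = 0L, chemicalZOffset = 0.8,
                          includeProtein = FALSE, nWaterMarkers = 64L,
                          seed = 1L) {
  if (length(compositionRatio) != 4L || any(compositionRatio < 0) ||
      all(compositionRatio == 0))
    stop("compositionRatio must be 4 nonnegative ratios, not all zero")
  if (apl < 40 || apl > 120)
    stop("apl must lie in [40, 120] Angstrom^2")
  if (lcPatchFraction < 0 || lcPatchFraction > 1)
    stop("lcPatchFraction must lie in [0, 1]")
  if (tiltDeg < 0 || tiltDeg > 90)
    stop("tiltDeg must lie in [0, 90] degrees")
  if (nLipidsPerLeaflet < 1L) stop("need at least one lipid")
  names(compositionRatio) <- c("DPPC", "POPC", "POPG", "CHOL")
  list(nLipidsPerLeaflet = as.integer(nLipidsPerLeaflet),
       compositionRatio = compositionRatio, apl = apl,
       lcPatchFraction = lcPatchFraction,
       latticeSpacing = latticeSpacing, tiltDeg = tiltDeg,
       nChemical = as.integer(nChemical),
       chemicalZOffset = chemicalZOffset,
       includeProtein = isTRUE(includeProtein),
       nWaterMarkers = as.integer(nWaterMarkers),
       seed = as.integer(seed))
}

## hexagonal strip wrapping the box in x: n sites in row-major order
.hex_strip_sites <- function(n, L, spacing, y0) {
  n_cols <- max(3L, as.integer(round(L / spacing)))
  sx <- L / n_cols
  dy <- spacing * sqrt(3) / 2
  n_rows <- ceiling(n / n_cols)
  if (n > 0 && n < 3L * n_cols)
    stop(sprintf("condensed patch of %d entities is below 3 wrapped rows (%d sites/row): too small for an unambiguous L_c phase at this box size",
                 n, n_cols))
  rows <- rep(seq_len(n_rows) - 1L, each = n_cols)[seq_len(n)]
  cols <- rep(seq_len(n_cols) - 1L, times = n_rows)[seq_len(n)]
  x <- (cols + 0.5 * (rows %% 2)) * sx
  y <- y0 + rows * dy
  list(xy = cbind(x %% L, y), height = n_rows * dy, sx = sx, dy = dy)
}

## jittered triangular lattice with spacing > eps inside a y band
.sparse_sites <- function(n, L, y_from, y_to) {
  if (n == 0L)
    return(matrix(numeric(0), ncol = 2))
  s <- .SPARSE_SPACING
  dy <- s * sqrt(3) / 2
  n_cols <- floor(L / s)
  n_rows <- floor((y_to - y_from) / dy) + 1L
  if (n_cols < 1L || n_rows < 1L || n_cols * n_rows < n)
    stop(sprintf("disordered region cannot hold %d entities at > %.2f nm spacing (capacity %d): area per lipid too small for the requested disordered fraction",
                 n, s, max(0L, n_cols * n_rows)))
  rows <- rep(seq_len(n_rows) - 1L, each = n_cols)[seq_len(n)]
  cols <- rep(seq_len(n_cols) - 1L, times = n_rows)[seq_len(n)]
  x <- (cols + 0.5 * (rows %% 2)) * s + s / 4
  y <- y_from + rows * dy
  jit <- matrix(stats::runif(2L * n, -.SPARSE_JITTER, .SPARSE_JITTER),
                ncol = 2)
  cbind((x + jit[, 1]) %% L, y + jit[, 2])
}

## split per-species molecule counts into patch/disordered sets whose
## entity sum (2 per phospholipid, 1 per cholesterol) best matches the
## requested fraction; condensed patch is filled DPPC-first
.split_patch <- function(counts, target_entities) {
  pl_avail <- c(DPPC = counts[["DPPC"]], POPC = counts[["POPC"]],
                POPG = counts[["POPG"]])
  chol_avail <- counts[["CHOL"]]
  k_pl <- min(sum(pl_avail), target_entities %/% 2L)
  rem <- target_entities - 2L * k_pl
  k_chol <- min(chol_avail, rem)
  patch_pl <- c(DPPC = 0L, POPC = 0L, POPG = 0L)
  left <- k_pl
  for (sp in names(pl_avail)) {
    take <- min(pl_avail[[sp]], left)
    patch_pl[sp] <- take
    left <- left - take
  }
  list(pl = patch_pl, chol = as.integer(k_chol),
       achieved = 2L * k_pl + as.integer(k_chol))
}

#' Build a synthetic monolayer frame with ground truth
#'
#' Two mirrored leaflets around a thin water-marker slab at the box
#' midplane. A share of the chain/sterol entities sits on a hexagonal
#' lattice patch (uniform tilt, collective azimuth); the remainder is
#' disordered (random tilt up to 60 degrees, random azimuth, all
#' pairwise spacings > 0.71 nm). Chain C10 markers sit exactly on their
#' lattice/disordered sites, so the DBSCAN packing geometry is exact by
#' construction. Chemical particles go at a fixed z offset from the
#' upper phosphate plane; an optional protein-like blob of heavy atoms
#' is inserted in the upper leaflet. The box is sized so the area per
#' lipid matches the spec exactly.
#'
#' The ground truth records achieved values (entity fraction, realized
#' mean tilt), so noiseless analysis round-trips recover them exactly.
#'
#' @param spec a [monolayerSpec()] list.
#' @return list with `frame` (a [MonolayerFrame-class]) and
#'   `groundTruth`.
#' @examples
#' b <- buildMonolayerFrame(monolayerSpec(nLipidsPerLeaflet = 60,
#'                                        lcPatchFraction = 1))
#' lcFraction(packingFraction(b$frame))
#' @export
buildMonolayerFrame <- function(spec) {
  .with_seed(spec$seed, .build_monolayer_impl(spec))
}

.build_monolayer_impl <- function(spec) {
  counts <- apportionComposition(spec$nLipidsPerLeaflet,
                                 spec$compositionRatio)
  n_pl <- sum(counts[c("DPPC", "POPC", "POPG")])
  n_entities <- 2L * n_pl + counts[["CHOL"]]
  L <- sqrt(spec$apl / 100 * spec$nLipidsPerLeaflet)
  box_z <- 2 * (.C1_Z + .CHAIN_LEN) + 2
  target <- as.integer(round(spec$lcPatchFraction * n_entities))
  split <- .split_patch(counts, target)

  patch <- if (split$achieved > 0L)
    .hex_strip_sites(split$achieved, L, spec$latticeSpacing, y0 = 0.3)
  else list(xy = matrix(numeric(0), ncol = 2), height = 0)
  if (split$achieved > 0L && 0.3 + patch$height > L)
    stop(sprintf("overfull lattice: a %.2f nm condensed patch does not fit the %.2f nm box (lattice spacing incompatible with the area per lipid)",
                 patch$height, L))
  n_sparse <- n_entities - split$achieved
  y_from <- if (split$achieved > 0L) 0.3 + patch$height + .PATCH_GAP
  else 0.4
  sparse <- .sparse_sites(n_sparse, L, y_from, L - 0.4)

  ## molecule roster per leaflet: patch molecules first (DPPC-first),
  ## then the disordered remainder
  roster <- c(rep("DPPC", split$pl[["DPPC"]]),
              rep("POPC", split$pl[["POPC"]]),
              rep("POPG", split$pl[["POPG"]]),
              rep("CHOL", split$chol),
              rep("DPPC", counts[["DPPC"]] - split$pl[["DPPC"]]),
              rep("POPC", counts[["POPC"]] - split$pl[["POPC"]]),
              rep("POPG", counts[["POPG"]] - split$pl[["POPG"]]),
              rep("CHOL", counts[["CHOL"]] - split$chol))
  n_patch_mol <- sum(split$pl) + split$chol
  sites <- rbind(patch$xy, sparse)

  atoms <- list()
  mol_id <- 0L
  tilts <- numeric(0)
  add <- function(name, res, sp, x, y, z, el = substr(name, 1, 1)) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      atomName = name, element = el, resName = res, species = sp,
      moleculeId = mol_id, x = x %% L, y = y %% L, z = z + box_z / 2)
  }
  chain_names <- list(c("C22", "C210", "C216"),
                      c("C32", "C310", "C316"))
  for (sgn in c(1, -1)) {
    cursor <- 0L
    for (m in seq_along(roster)) {
      sp <- roster[m]
      in_patch <- m <= n_patch_mol
      mol_id <- mol_id + 1L
      if (sp == "CHOL") {
        site <- sites[cursor + 1L, ]; cursor <- cursor + 1L
        add("O3", "CHOL", "CHOL", site[1], site[2], sgn * .HEAD_Z,
            el = "O")
        add("C14", "CHOL", "CHOL", site[1], site[2], sgn * 1.6)
      } else {
        s1 <- sites[cursor + 1L, ]; s2 <- sites[cursor + 2L, ]
        cursor <- cursor + 2L
        add("P", sp, sp, (s1[1] + s2[1]) / 2, (s1[2] + s2[2]) / 2,
            sgn * .HEAD_Z)
        for (ch in 1:2) {
          site <- if (ch == 1L) s1 else s2
          theta <- if (in_patch) spec$tiltDeg * pi / 180 else
            stats::runif(1, 0, 60) * pi / 180
          phi <- if (in_patch) 0 else stats::runif(1, 0, 2 * pi)
          tilts <- c(tilts, theta * 180 / pi)
          u <- c(cos(phi), sin(phi))
          z1 <- sgn * .C1_Z
          c1_xy <- site - .C10_FRAC * .CHAIN_LEN * sin(theta) * u
          dz10 <- sgn * .C10_FRAC * .CHAIN_LEN * cos(theta)
          nm3 <- chain_names[[ch]]
          add(nm3[1], sp, sp, c1_xy[1], c1_xy[2], z1)
          add(nm3[2], sp, sp, site[1], site[2], z1 + dz10)
          add(nm3[3], sp, sp,
              c1_xy[1] + .CHAIN_LEN * sin(theta) * u[1],
              c1_xy[2] + .CHAIN_LEN * sin(theta) * u[2],
              z1 + sgn * .CHAIN_LEN * cos(theta))
        }
      }
    }
  }
  ## water marker slab at the midplane
  ng <- ceiling(sqrt(spec$nWaterMarkers))
  gx <- ((seq_len(spec$nWaterMarkers) - 1L) %% ng + 0.5) * L / ng
  gy <- ((seq_len(spec$nWaterMarkers) - 1L) %/% ng + 0.5) * L / ng
  for (w in seq_len(spec$nWaterMarkers)) {
    mol_id <- mol_id + 1L
    add("OW", "SOL", "WATER", gx[w], gy[w], 0, el = "O")
  }
  if (spec$nChemical > 0L) {
    cx <- stats::runif(spec$nChemical, 0, L)
    cy <- stats::runif(spec$nChemical, 0, L)
    for (k in seq_len(spec$nChemical)) {
      mol_id <- mol_id + 1L
      add("CB", "CHEM", "CHEMICAL", cx[k], cy[k],
          .HEAD_Z + spec$chemicalZOffset)
    }
  }
  if (spec$includeProtein) {
    n_blob <- 40L
    th <- stats::runif(n_blob, 0, pi)
    ph <- stats::runif(n_blob, 0, 2 * pi)
    r <- 0.5 * stats::runif(n_blob)^(1 / 3)
    mol_id <- mol_id + 1L
    for (k in seq_len(n_blob))
      add("CA", "PROT", "PROTEIN",
          L / 2 + r[k] * sin(th[k]) * cos(ph[k]),
          L / 2 + r[k] * sin(th[k]) * sin(ph[k]),
          2.4 + r[k] * cos(th[k]))
  }
  tab <- do.call(rbind, atoms)
  frame <- MonolayerFrame(
    coords = cbind(tab$x, tab$y, tab$z), atomName = tab$atomName,
    element = tab$element, resName = tab$resName, species = tab$species,
    moleculeId = tab$moleculeId, box = c(L, L, box_z))
  gt <- list(
    true_lc_fraction = split$achieved / n_entities,
    requested_lc_fraction = spec$lcPatchFraction,
    true_tilt_deg = mean(tilts),
    patch_tilt_deg = spec$tiltDeg,
    n_entities_per_leaflet = n_entities,
    composition_counts = as.list(counts),
    apl = spec$apl, box_xy = L,
    n_chemical = spec$nChemical,
    chemical_z_offset = spec$chemicalZOffset,
    include_protein = spec$includeProtein, seed = spec$seed)
  list(frame = frame, groundTruth = gt)
}

#' Simulate a monolayer compression series with constructed contacts
#'
#' Starting from a disordered frame at `aplStart`, produces frames whose
#' area per lipid decreases linearly to `aplEnd` (the dynamic-protocol
#' band, 110 to 54.5 Angstrom^2 by default) by rescaling the box and
#' all in-plane positions affinely, preserving z. A line of
#' protein-probe atoms plus `nChemical` chemical particles is added with
#' constructed placements: in frame i, exactly k_i chemicals sit 0.45 nm
#' above distinct probe atoms (one contact pair each) and the rest are
#' parked out of range, with k_i increasing linearly as the area
#' shrinks, so the normalized contacts-versus-area series has the
#' closed form k_i / (n_probe x n_chemical).
#'
#' @param spec a [monolayerSpec()] for the base frame (chemicals and
#'   protein in the spec are ignored; the series places its own).
#' @param aplStart,aplEnd series endpoints, Angstrom^2.
#' @param nFrames number of frames, >= 2.
#' @param nChemical chemical particles per frame.
#' @param nProbe protein probe atoms.
#' @return list with `frames`, `groundTruth` (per-frame APL, contact
#'   pair counts k, normalized contacts).
#' @export
simulateCompressionSeries <- function(spec = monolayerSpec(
                                        compositionRatio = c(60, 20, 10,
                                                             10),
                                        apl = 110,
                                        lcPatchFraction = 0),
                                      aplStart = 110, aplEnd = 54.5,
                                      nFrames = 12L, nChemical = 20L,
                                      nProbe = 10L) {
  if (nFrames < 2L) stop("need at least 2 frames")
  if (aplStart <= aplEnd || aplEnd <= 0)
    stop("require aplStart > aplEnd > 0")
  spec$apl <- aplStart
  spec$nChemical <- 0L
  spec$includeProtein <- FALSE
  base <- buildMonolayerFrame(spec)
  fr0 <- base$frame
  L0 <- fr0@box[1]
  probe_x <- (seq_len(nProbe) - 0.5) * L0 / nProbe
  probe_y <- rep(L0 / 2, nProbe)
  probe_z <- rep(fr0@box[3] / 2 + 2.5, nProbe)
  apl_seq <- seq(aplStart, aplEnd, length.out = nFrames)
  k_seq <- as.integer(round((nChemical * (aplStart - apl_seq)) /
                              (aplStart - aplEnd)))
  k_seq <- pmin(k_seq, min(nChemical, nProbe))
  chem_far_z <- fr0@box[3] / 2 + 2.5 + 2.0
  frames <- vector("list", nFrames)
  for (i in seq_len(nFrames)) {
    sc <- sqrt(apl_seq[i] / aplStart)
    k <- k_seq[i]
    cx <- c(probe_x[seq_len(k)],
            ((seq_len(nChemical - k) - 0.5) * L0 / nChemical))
    cy <- c(probe_y[seq_len(k)], rep(L0 / 4, nChemical - k))
    cz <- c(probe_z[seq_len(k)] + 0.45, rep(chem_far_z, nChemical - k))
    xyz <- rbind(fr0@coords,
                 cbind(probe_x, probe_y, probe_z),
                 cbind(cx, cy, cz))
    xyz[, 1:2] <- xyz[, 1:2] * sc
    n0 <- nrow(fr0@coords)
    frames[[i]] <- MonolayerFrame(
      coords = xyz,
      atomName = c(fr0@atomName, rep("CA", nProbe),
                   rep("CB", nChemical)),
      element = c(fr0@element, rep("C", nProbe + nChemical)),
      resName = c(fr0@resName, rep("PROT", nProbe),
                  rep("CHEM", nChemical)),
      species = c(fr0@species, rep("PROTEIN", nProbe),
                  rep("CHEMICAL", nChemical)),
      moleculeId = c(fr0@moleculeId,
                     rep(max(fr0@moleculeId) + 1L, nProbe),
                     max(fr0@moleculeId) + 1L + seq_len(nChemical)),
      box = c(fr0@box[1] * sc, fr0@box[2] * sc, fr0@box[3]),
      frameTime = i - 1)
  }
  gt <- list(apl = apl_seq, k_contacts = k_seq,
             contacts_true = k_seq / (nProbe * nChemical),
             n_probe = nProbe, n_chemical = nChemical,
             apl_start = aplStart, apl_end = aplEnd,
             base = base$groundTruth)
  list(frames = frames, groundTruth = gt)
}
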