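.LIPID_SPECIES <- c("DPPC", "POPC", "POPG", "CHOL")
.PL_SPECIES <- c("DPPC", "POPC", "POPG")

## squared periodic minimum-image distances between two coordinate sets
## (matrix result); dims = columns used, box lengths recycled per dim
.min_image_dist2 <- function(xa, xb, box) {
  d2 <- 0
  for (k in seq_along(box)) {
    d <- abs(outer(xa[, k], xb[, k], `-`))
    d <- pmin(d, box[k] - d)
    d2 <- d2 + d * d
  }
  d2
}

#' Assign lipids to monolayer leaflets
#'
#' The simulated systems hold two monolayers with their headgroups
#' facing a central water slab. Each lipid's head marker (phosphate for
#' phospholipids, the O3 hydroxyl for cholesterol, else the molecule's
#' first atom) is compared against the water-slab center (or an explicit
#' midplane): above is `upper`, below is `lower`; a head exactly at the
#' midplane goes to `upper` with a warning.
#'
#' @param frame a [MonolayerFrame-class].
#' @param midplane optional explicit z midplane (nm); required when the
#'   frame has no water.
#' @param speciesMap species map, see [defaultSpeciesMap()].
#' @return data.frame: `moleculeId`, `species`, `leaflet`, `headZ`.
#' @export
assignLeaflets <- function(frame, midplane = NULL,
                           speciesMap = defaultSpeciesMap()) {
  stopifnot(is(frame, "MonolayerFrame"))
  if (is.null(midplane)) {
    wz <- frame@coords[frame@species == "WATER", 3]
    if (!length(wz))
      stop("frame has no water to locate the midplane; pass `midplane` explicitly")
    midplane <- mean(wz)
  }
  is_lip <- frame@species %in% .LIPID_SPECIES
  mol <- frame@moleculeId[is_lip]
  sp <- frame@species[is_lip]
  nm <- frame@atomName[is_lip]
  z <- frame@coords[is_lip, 3]
  roles <- speciesMap$roles
  head_names <- roles$atom[roles$role %in% c("phosphate", "chol_head")]
  ord <- order(mol, !(nm %in% head_names))  # head markers first
  first_of_mol <- !duplicated(mol[ord])
  out <- data.frame(moleculeId = mol[ord][first_of_mol],
                    species = sp[ord][first_of_mol],
                    headZ = z[ord][first_of_mol])
  out$leaflet <- ifelse(out$headZ > midplane, "upper", "lower")
  at_mid <- out$headZ == midplane
  if (any(at_mid)) {
    out$leaflet[at_mid] <- "upper"
    warning(sprintf("%d lipid head(s) exactly at the midplane assigned to the upper leaflet",
                    sum(at_mid)))
  }
  out[order(out$moleculeId), ]
}

#' Area per lipid of one leaflet
#'
#' In-plane box area divided by the number of lipids in the leaflet,
#' converted from nm^2 to Angstrom^2 (the unit the field reports APL
#' in).
#'
#' @param frame a [MonolayerFrame-class].
#' @param leaflet `"upper"` or `"lower"`.
#' @param leaflets optional precomputed [assignLeaflets()] table.
#' @param midplane optional midplane passed through to
#'   [assignLeaflets()].
#' @return APL in Angstrom^2.
#' @examples
#' ## a 9.05 x 9.05 nm box with 149 lipids gives ~55 A^2 per lipid
#' @export
areaPerLipid <- function(frame, leaflet = "upper", leaflets = NULL,
                         midplane = NULL) {
  if (is.null(leaflets))
    leaflets <- assignLeaflets(frame, midplane = midplane)
  n <- sum(leaflets$leaflet == leaflet)
  if (n == 0L)
    stop(sprintf("no lipids in the %s leaflet", leaflet))
  frame@box[1] * frame@box[2] * 100 / n
}

## marker table: one row per packing entity (acyl chain mid-carbon or
## cholesterol C14) of the requested leaflet
.packing_markers <- function(frame, leaflet, leaflets, speciesMap) {
  roles <- speciesMap$roles
  mid_names <- roles$atom[roles$role == "mid"]
  chol_names <- roles$atom[roles$role == "chol_marker"]
  keep_mol <- leaflets$moleculeId[leaflets$leaflet == leaflet]
  is_marker <- (frame@species %in% .PL_SPECIES &
                  frame@atomName %in% mid_names) |
    (frame@species == "CHOL" & frame@atomName %in% chol_names)
  sel <- which(is_marker & frame@moleculeId %in% keep_mol)
  pl_mols <- unique(frame@moleculeId[frame@species %in% .PL_SPECIES &
                                       frame@moleculeId %in% keep_mol])
  if (length(pl_mols)) {
    per_mol <- table(frame@moleculeId[sel][
      frame@species[sel] %in% .PL_SPECIES])
    if (length(per_mol) < length(pl_mols) || any(per_mol != 2L))
      stop(sprintf("phospholipid chain marker atoms (%s) unresolvable for some molecules",
                   paste(mid_names, collapse = "/")))
  }
  data.frame(index = sel, moleculeId = frame@moleculeId[sel],
             species = frame@species[sel],
             x = frame@coords[sel, 1], y = frame@coords[sel, 2])
}

#' Liquid-condensed packing fraction by periodic DBSCAN
#'
#' Clusters the in-plane positions of the 10th acyl carbon of every
#' phospholipid chain and the C14 atom of every cholesterol (one entity
#' per chain or sterol) with DBSCAN under periodic minimum-image
#' distances in x,y. A point is a core point when at least
#' `minNeighbors` other points lie within `eps` (set
#' `includeSelf = TRUE` to count the point itself, the alternative
#' reading); border points joined to a cluster count as condensed unless
#' `countBorder = FALSE`. Any entity in a cluster is assigned to the
#' L_c (tightly packed) phase; the L_c fraction is the labelled share of
#' entities.
#'
#' @param frame a [MonolayerFrame-class].
#' @param leaflet `"upper"` or `"lower"`.
#' @param eps clustering cutoff, nm (default 0.71).
#' @param minNeighbors neighbor requirement (default 6).
#' @param includeSelf count the point itself toward `minNeighbors`
#'   (default FALSE).
#' @param countBorder count border points as condensed (default TRUE).
#' @param leaflets,midplane,speciesMap see [assignLeaflets()].
#' @return A [PackingResult-class]. Fewer than `minNeighbors + 1`
#'   entities yield L_c fraction 0 with a warning.
#' @export
packingFraction <- function(frame, leaflet = "upper", eps = 0.71,
                            minNeighbors = 6L, includeSelf = FALSE,
                            countBorder = TRUE, leaflets = NULL,
                            midplane = NULL,
                            speciesMap = defaultSpeciesMap()) {
  stopifnot(is(frame, "MonolayerFrame"))
  if (is.null(leaflets))
    leaflets <- assignLeaflets(frame, midplane = midplane,
                               speciesMap = speciesMap)
  ent <- .packing_markers(frame, leaflet, leaflets, speciesMap)
  n <- nrow(ent)
  if (n < minNeighbors + 1L) {
    warning(sprintf("only %d clustering entities (< minNeighbors + 1); L_c fraction 0",
                    n))
    return(new("PackingResult", lcFraction = 0, nEntities = as.integer(n),
               clusterLabels = rep(-1L, n), entityTable = ent))
  }
  labels <- .dbscan_periodic(cbind(ent$x, ent$y), frame@box[1:2], eps,
                             as.integer(minNeighbors), includeSelf,
                             countBorder)
  new("PackingResult",
      lcFraction = sum(labels >= 0L) / n,
      nEntities = as.integer(n), clusterLabels = labels,
      entityTable = ent)
}

## DBSCAN with periodic minimum-image metric. Queue expansion over core
## points; border points adopt the cluster of the first core point that
## reaches them. labels: -1 noise, 0.. cluster ids.
.dbscan_periodic <- function(xy, box, eps, minNeighbors, includeSelf,
                             countBorder) {
  n <- nrow(xy)
  d2 <- .min_image_dist2(xy, xy, box)
  adj <- d2 <= eps * eps
  diag(adj) <- includeSelf
  deg <- rowSums(adj)
  core <- deg >= minNeighbors
  labels <- rep(-1L, n)
  cluster <- -1L
  for (s in which(core)) {
    if (labels[s] >= 0L) next
    cluster <- cluster + 1L
    labels[s] <- cluster
    queue <- s
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[p, ])
      newly <- nb[labels[nb] < 0L]
      labels[newly] <- cluster
      queue <- c(queue, newly[core[newly]])
    }
  }
  if (!countBorder)
    labels[!core & labels >= 0L] <- -1L
  labels
}

#' Time-averaged packing fraction over frames
#'
#' @param frames list of [MonolayerFrame-class] objects.
#' @param ... passed to [packingFraction()].
#' @return list with `mean`, `sd` and the per-frame fractions.
#' @export
packingFractionSeries <- function(frames, ...) {
  fr <- vapply(frames, function(f) lcFraction(packingFraction(f, ...)),
               numeric(1))
  list(mean = mean(fr), sd = stats::sd(fr), perFrame = fr)
}

#' Acyl chain tilt relative to the monolayer normal
#'
#' For every phospholipid chain, the angle between the vector from the
#' first to the 16th chain carbon and the z axis (the monolayer normal),
#' folded to [0, 90] degrees so leaflet orientation and chain direction
#' conventions cannot flip the sign. Cholesterol is excluded. The mean
#' is the arithmetic mean over chains (two per phospholipid).
#'
#' @param frame a [MonolayerFrame-class].
#' @param leaflet `"upper"`, `"lower"` or NULL for all chains.
#' @param leaflets,midplane,speciesMap see [assignLeaflets()].
#' @return A [TiltResult-class].
#' @export
chainTilt <- function(frame, leaflet = NULL, leaflets = NULL,
                      midplane = NULL,
                      speciesMap = defaultSpeciesMap()) {
  stopifnot(is(frame, "MonolayerFrame"))
  roles <- speciesMap$roles
  keep_mol <- if (is.null(leaflet)) unique(frame@moleculeId) else {
    if (is.null(leaflets))
      leaflets <- assignLeaflets(frame, midplane = midplane,
                                 speciesMap = speciesMap)
    leaflets$moleculeId[leaflets$leaflet == leaflet]
  }
  is_pl <- frame@species %in% .PL_SPECIES &
    frame@moleculeId %in% keep_mol
  tilts <- numeric(0)
  for (ch in sort(unique(roles$chain[!is.na(roles$chain)]))) {
    first_nm <- roles$atom[roles$role == "first" & roles$chain == ch]
    last_nm <- roles$atom[roles$role == "last" & roles$chain == ch]
    i1 <- which(is_pl & frame@atomName %in% first_nm)
    i2 <- which(is_pl & frame@atomName %in% last_nm)
    if (!length(i1) && !length(i2)) next
    m1 <- frame@moleculeId[i1]
    m2 <- frame@moleculeId[i2]
    if (length(i1) != length(i2) || !all(sort(m1) == sort(m2)))
      stop(sprintf("chain %d markers incomplete: first (%s) and 16th (%s) carbons must pair per molecule",
                   ch, paste(first_nm, collapse = "/"),
                   paste(last_nm, collapse = "/")))
    i1 <- i1[order(m1)]; i2 <- i2[order(m2)]
    v <- frame@coords[i2, , drop = FALSE] -
      frame@coords[i1, , drop = FALSE]
    ## chains crossing the periodic boundary carry wrapped coordinates
    for (k in 1:2)
      v[, k] <- v[, k] - frame@box[k] * round(v[, k] / frame@box[k])
    nv <- sqrt(rowSums(v^2))
    tilts <- c(tilts, acos(pmin(1, abs(v[, 3]) / nv)) * 180 / pi)
  }
  if (!length(tilts))
    stop("no phospholipid chain markers found (missing 16th-carbon marker?)")
  new("TiltResult", meanTilt = mean(tilts), perChainTilt = tilts,
      nChains = length(tilts))
}

#' Normalized number-density profiles along the monolayer normal
#'
#' Histograms atom positions of each species group along z. Every frame
#' is first shifted so the mean phosphate z of the chosen leaflet sits
#' at 0 (per-frame centering removes drift), counts accumulate over
#' frames, and each species curve is divided by its maximum so occupied
#' profiles peak at exactly 1. A requested species with no atoms yields
#' an all-zero profile and is flagged, not an error.
#'
#' @param frames list of [MonolayerFrame-class] objects.
#' @param speciesGroups named list of species-label vectors; default
#'   profiles every species present plus the standard groups.
#' @param binWidth bin width, nm (default 0.1).
#' @param leaflet leaflet whose phosphate plane defines z = 0.
#' @param restrictSide keep only atoms on the leaflet's side of the
#'   water midplane when water is present (default TRUE).
#' @param speciesMap see [defaultSpeciesMap()].
#' @return A [DensityProfile-class].
#' @export
densityProfile <- function(frames, speciesGroups = NULL, binWidth = 0.1,
                           leaflet = "upper", restrictSide = TRUE,
                           speciesMap = defaultSpeciesMap()) {
  if (is(frames, "MonolayerFrame")) frames <- list(frames)
  if (!length(frames)) stop("need at least one frame")
  if (is.null(speciesGroups)) {
    present <- unique(unlist(lapply(frames, function(f) f@species)))
    speciesGroups <- stats::setNames(as.list(present), present)
  }
  roles <- speciesMap$roles
  p_names <- roles$atom[roles$role == "phosphate"]
  shifted <- lapply(frames, function(fr) {
    leaf <- assignLeaflets(fr, midplane = .water_midplane(fr),
                           speciesMap = speciesMap)
    keep_mol <- leaf$moleculeId[leaf$leaflet == leaflet]
    pz <- fr@coords[fr@atomName %in% p_names &
                      fr@moleculeId %in% keep_mol, 3]
    if (!length(pz))
      stop(sprintf("no phosphate marker atoms in the %s leaflet to center on",
                   leaflet))
    z <- fr@coords[, 3] - mean(pz)
    side <- rep(TRUE, length(z))
    wz <- fr@coords[fr@species == "WATER", 3] - mean(pz)
    if (restrictSide && length(wz)) {
      mid <- mean(wz)
      side <- if (leaflet == "upper") z >= mid else z <= mid
      side[fr@species == "WATER"] <- TRUE
    }
    list(z = z, species = fr@species, keep = side)
  })
  all_z <- unlist(lapply(shifted, function(s) s$z[s$keep]))
  lo <- floor(min(all_z) / binWidth) * binWidth - binWidth / 2
  hi <- ceiling(max(all_z) / binWidth) * binWidth + binWidth / 2
  breaks <- seq(lo, hi + binWidth, by = binWidth)
  centers <- head(breaks, -1) + binWidth / 2
  counts <- matrix(0, nrow = length(centers),
                   ncol = length(speciesGroups),
                   dimnames = list(NULL, names(speciesGroups)))
  for (s in shifted) {
    for (g in names(speciesGroups)) {
      zz <- s$z[s$keep & s$species %in% speciesGroups[[g]]]
      if (length(zz)) {
        idx <- findInterval(zz, breaks, rightmost.closed = TRUE)
        counts[, g] <- counts[, g] +
          tabulate(idx, nbins = length(centers))
      }
    }
  }
  maxima <- apply(counts, 2, max)
  empty <- names(speciesGroups)[maxima == 0]
  density <- counts
  for (g in names(speciesGroups))
    if (maxima[g] > 0) density[, g] <- counts[, g] / maxima[g]
  new("DensityProfile", zGrid = centers, density = density,
      counts = counts, binWidth = binWidth, emptySpecies = empty)
}

.water_midplane <- function(frame) {
  wz <- frame@coords[frame@species == "WATER", 3]
  if (length(wz)) mean(wz) else 0
}

## resolve a group selection (species names, logical mask or indices)
## to heavy-atom indices
.resolve_selection <- function(frame, sel, label) {
  idx <- if (is.character(sel)) which(frame@species %in% sel)
  else if (is.logical(sel)) which(sel)
  else as.integer(sel)
  idx <- idx[frame@element[idx] != "H"]
  if (!length(idx))
    stop(sprintf("selection %s is empty after hydrogen exclusion", label))
  idx
}

#' Partner-normalized heavy-atom contact count
#'
#' Counts heavy-atom pairs (one atom from each group) within the cutoff
#' under periodic minimum-image distances in x, y and z, normalized by
#' the number of possible interaction partners, N_heavy(A) x N_heavy(B).
#' Hydrogens are excluded; overlapping or empty groups are selection
#' errors. Per-molecule-pair normalization is available via
#' `perMolecule`.
#'
#' @param frame a [MonolayerFrame-class].
#' @param groupA,groupB species name(s), logical mask or atom indices.
#' @param cutoff contact distance, nm (default 0.6).
#' @param perMolecule normalize by molecule-pair count instead of
#'   atom-pair count.
#' @return Normalized contact value (attributes `n_pairs`, `n_a`,
#'   `n_b`).
#' @export
contactCount <- function(frame, groupA, groupB, cutoff = 0.6,
                         perMolecule = FALSE) {
  stopifnot(is(frame, "MonolayerFrame"))
  ia <- .resolve_selection(frame, groupA, "groupA")
  ib <- .resolve_selection(frame, groupB, "groupB")
  if (length(intersect(ia, ib)))
    stop("groups overlap: contact groups must be disjoint")
  d2 <- .min_image_dist2(frame@coords[ia, , drop = FALSE],
                         frame@coords[ib, , drop = FALSE], frame@box)
  n_pairs <- sum(d2 <= cutoff * cutoff)
  denom <- if (perMolecule)
    length(unique(frame@moleculeId[ia])) *
      length(unique(frame@moleculeId[ib]))
  else length(ia) * length(ib)
  structure(n_pairs / denom, n_pairs = n_pairs, n_a = length(ia),
            n_b = length(ib))
}

#' Contacts versus monolayer area for a compression series
#'
#' For every frame of a compression series, computes the area per lipid
#' and the normalized contact value for one group pair, then averages
#' the contact values within the supplied APL bins. Empty bins are
#' dropped from the grid and flagged; frames outside the bin range are
#' counted, not an error.
#'
#' @param frames list of [MonolayerFrame-class] objects with per-frame
#'   boxes.
#' @param groupA,groupB contact selections, see [contactCount()].
#' @param aplBreaks APL bin edges, Angstrom^2, increasing.
#' @param cutoff contact cutoff, nm.
#' @param leaflet leaflet for the APL computation.
#' @param midplane optional explicit midplane for leaflet assignment.
#' @param groupPair length-2 labels stored in the result.
#' @return A [ContactSeries-class] (single replica; `error` = 0).
#' @export
contactsVsArea <- function(frames, groupA, groupB, aplBreaks,
                           cutoff = 0.6, leaflet = "upper",
                           midplane = NULL,
                           groupPair = c("groupA", "groupB")) {
  if (length(aplBreaks) < 2L || is.unsorted(aplBreaks, strictly = TRUE))
    stop("aplBreaks must be increasing bin edges")
  apl <- vapply(frames, function(f)
    areaPerLipid(f, leaflet, midplane = midplane), numeric(1))
  cc <- vapply(frames, function(f)
    as.numeric(contactCount(f, groupA, groupB, cutoff)), numeric(1))
  bin <- findInterval(apl, aplBreaks, rightmost.closed = TRUE)
  in_range <- bin >= 1L & bin <= length(aplBreaks) - 1L
  n_out <- sum(!in_range)
  centers <- (head(aplBreaks, -1) + aplBreaks[-1]) / 2
  means <- tapply(cc[in_range], factor(bin[in_range],
                                       levels = seq_along(centers)),
                  mean)
  empty <- which(is.na(means))
  keep <- !is.na(means)
  new("ContactSeries", aplGrid = centers[keep],
      contacts = as.numeric(means[keep]),
      error = rep(0, sum(keep)), groupPair = groupPair,
      emptyBins = as.integer(empty), nOutOfRange = as.integer(n_out))
}

#' Aggregate two replica contact series
#'
#' The duplicate-simulation convention: the reported value per APL bin
#' is the replica mean and the error estimate is half the absolute
#' difference between replicas.
#'
#' @param series1,series2 [ContactSeries-class] objects on identical
#'   APL grids for the same group pair.
#' @return A [ContactSeries-class] with `error` filled in.
#' @export
replicaAggregate <- function(series1, series2) {
  stopifnot(is(series1, "ContactSeries"), is(series2, "ContactSeries"))
  if (length(series1@aplGrid) != length(series2@aplGrid) ||
      any(series1@aplGrid != series2@aplGrid))
    stop("replica APL grids do not align")
  if (!identical(series1@groupPair, series2@groupPair))
    stop("replicas describe different group pairs")
  new("ContactSeries", aplGrid = series1@aplGrid,
      contacts = (series1@contacts + series2@contacts) / 2,
      error = abs(series1@contacts - series2@contacts) / 2,
      groupPair = series1@groupPair,
      emptyBins = union(series1@emptyBins, series2@emptyBins),
      nOutOfRange = series1@nOutOfRange + series2@nOutOfRange)
}
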