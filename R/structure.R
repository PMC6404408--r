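#' Read a protein structure from a PDB file or text
#'
#' Ingests ATOM records (first MODEL only for multi-model NMR entries), keeps
#' heavy atoms, and drops residues that lack a C-alpha atom (with a warning).
#' Alternate locations other than blank or "A" are discarded.
#'
#' @param pdb either a path to a PDB file or a character vector of PDB lines.
#' @param source free-text provenance label stored on the object; defaults to
#'   the file name or "text".
#' @return An object of class \code{"fibril_structure"}: a list with
#'   \itemize{
#'     \item \code{atoms}: data.frame with columns \code{chain}, \code{resno}
#'       (author numbering), \code{ridx} (1-based sequential index within the
#'       chain), \code{resid}, \code{elety} (atom name), \code{elesy}
#'       (element), \code{x}, \code{y}, \code{z};
#'     \item \code{residues}: data.frame with one row per residue (\code{bead},
#'       \code{chain}, \code{resno}, \code{ridx}) in bead order;
#'     \item \code{n_chains}, \code{chains}, \code{source}.
#'   }
#' @export
read_structure <- function(pdb, source = NULL) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    if (is.null(source)) source <- basename(path)
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n"))
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path), add = TRUE)
    if (is.null(source)) source <- "text"
  }
  p <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("unparsable PDB input: ", conditionMessage(e)))
  at <- p$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records found in PDB input")
  # heavy atoms only
  elesy <- at$elesy
  noel <- is.na(elesy) | elesy == ""
  if (any(noel)) elesy[noel] <- substr(gsub("[0-9]", "", trimws(at$elety[noel])), 1, 1)
  keep <- !(toupper(elesy) %in% c("H", "D"))
  # altLoc: blank or A
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  elesy <- toupper(elesy[keep])
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(chain = chain, resno = at$resno, resid = at$resid,
                      elety = trimws(at$elety), elesy = elesy,
                      x = at$x, y = at$y, z = at$z,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      stringsAsFactors = FALSE)
  .finish_structure(atoms, source)
}

# assemble + validate the structure object from an atom table
.finish_structure <- function(atoms, source) {
  # residue key preserving file order
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  ukey <- unique(key)
  has_ca <- vapply(ukey, function(k) any(atoms$elety[key == k] == "CA"), logical(1))
  if (any(!has_ca)) {
    warning(sum(!has_ca), " residue(s) without a C-alpha atom dropped")
    atoms <- atoms[key %in% ukey[has_ca], , drop = FALSE]
    key <- key[key %in% ukey[has_ca]]
    ukey <- ukey[has_ca]
  }
  if (length(ukey) == 0) stop("no residues with a C-alpha atom found")
  n_ca <- vapply(ukey, function(k) sum(atoms$elety[key == k] == "CA"), integer(1))
  if (any(n_ca != 1)) stop("residue(s) with multiple C-alpha atoms: ",
                           paste(ukey[n_ca != 1], collapse = ", "))
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates in input")
  # 1-based sequential residue index within each chain, in file order
  chains <- unique(atoms$chain)
  ridx <- integer(nrow(atoms))
  residues <- NULL
  bead <- 0L
  for (ch in chains) {
    cu <- ukey[vapply(strsplit(ukey, "\\|"), `[`, "", 1) == ch]
    for (i in seq_along(cu)) {
      sel <- key == cu[i]
      ridx[sel] <- i
      bead <- bead + 1L
      residues <- rbind(residues, data.frame(
        bead = bead, chain = ch, resno = atoms$resno[sel][1], ridx = i,
        stringsAsFactors = FALSE))
    }
  }
  atoms$ridx <- ridx
  atoms$insert <- NULL
  structure(list(atoms = atoms, residues = residues,
                 chains = chains, n_chains = length(chains),
                 source = source),
            class = "fibril_structure")
}

#' @export
print.fibril_structure <- function(x, ...) {
  cat(sprintf("fibril_structure: %d chain(s), %d residues, %d heavy atoms [%s]\n",
              x$n_chains, nrow(x$residues), nrow(x$atoms), x$source))
  invisible(x)
}

#' C-alpha coordinates of a structure, one bead per residue
#'
#' @param structure a \code{fibril_structure}.
#' @return Numeric matrix (n_residues x 3) in bead order.
#' @export
calpha_coords <- function(structure) {
  at <- structure$atoms
  ca <- at[at$elety == "CA", , drop = FALSE]
  key <- paste(ca$chain, ca$ridx)
  ord <- match(paste(structure$residues$chain, structure$residues$ridx), key)
  m <- as.matrix(ca[ord, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Write a structure to a PDB file
#'
#' Emits fixed-width ATOM records through \code{bio3d::write.pdb}.
#'
#' @param structure a \code{fibril_structure}.
#' @param file output path.
#' @return Invisibly, the path.
#' @export
write_structure_pdb <- function(structure, file) {
  at <- structure$atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz, type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$elety, eleno = seq_len(nrow(at)),
                   elesy = at$elesy)
  invisible(file)
}

#' Generate a synthetic cross-beta fibril
#'
#' Builds an idealised amyloid-like fibril: \code{n_layers} stacked layers of
#' chains with a regular axial rise along z, optionally several laterally
#' packed protofilaments along y. By default each chain folds into a two-strand
#' beta-arch (hairpin) whose arms are extended strands with a 3.8 A C-alpha
#' step, so that intrachain (across the arch), interchain (between
#' protofilaments) and intersheet (between layers) native contacts all occur.
#' Each body residue carries three heavy atoms: the C-alpha trace (pleated,
#' as in a real strand), a pseudo-C-beta side chain alternating into the
#' steric-zipper interfaces between arms and protofilaments, and a pseudo
#' backbone carbonyl O pointing along the stacking axis, which bridges
#' adjacent layers the way the inter-strand hydrogen-bond ladder does.
#'
#' With \code{n_tail > 0}, each chain additionally carries that many trailing
#' residues splayed away from the fibril body, emulating disordered terminal
#' segments that form (almost) no native contacts.
#'
#' @param n_layers number of stacked layers (>= 2).
#' @param n_protofilaments laterally packed protofilaments per layer (>= 1).
#' @param residues_per_chain residues in the folded body of each chain (>= 5).
#' @param rise axial rise between consecutive layers, A.
#' @param lateral_spacing centre-to-centre protofilament spacing, A.
#' @param seed integer; deterministic coordinate jitter (<= 0.05 A per
#'   coordinate) breaking exact degeneracies.
#' @param fold \code{"hairpin"} (default) or \code{"strand"} for a single
#'   extended strand (such a chain has no intrachain contacts).
#' @param n_tail disordered tail residues appended per chain.
#' @param ca_step C-alpha step along a strand, A.
#' @return A \code{fibril_structure} with \code{source = "synthetic"}.
#' @export
generate_synthetic_fibril <- function(n_layers, n_protofilaments = 1,
                                      residues_per_chain = 12,
                                      rise = 4.8, lateral_spacing = 9.0,
                                      seed = 1, fold = c("hairpin", "strand"),
                                      n_tail = 0, ca_step = 3.8) {
  fold <- match.arg(fold)
  if (n_layers < 2) stop("n_layers must be >= 2")
  if (residues_per_chain < 5) stop("residues_per_chain must be >= 5")
  if (n_protofilaments < 1) stop("n_protofilaments must be >= 1")
  if (rise <= 0 || lateral_spacing <= 0 || ca_step <= 0)
    stop("geometry parameters must be positive")

  n <- residues_per_chain
  arm_sep <- 4.5   # beta-arch arm separation, A
  cb_len <- 2.0    # pseudo-C-beta offset along the stacking axis, A

  # One chain template at the origin, emulating a pleated beta-strand in a
  # cross-beta fold. Per body residue three heavy atoms:
  #   CA  - pleated trace: strand along x, pleat (zigzag, amplitude zig)
  #         alternating in y, so consecutive triplets are never collinear and
  #         dihedrals are well defined; the bond step stays ca_step.
  #   CB  - pseudo side chain along +-y (the pleat side), reaching into the
  #         steric-zipper interfaces between arms and protofilaments, as real
  #         side chains point perpendicular to the sheet plane. Near the
  #         hairpin turn CB flips outward (turn side chains are solvent-faced
  #         and those residue pairs are below the sequence-separation cut).
  #   O   - pseudo backbone carbonyl along +z, bridging to the next layer the
  #         way the inter-strand hydrogen-bond ladder does.
  # Tail residues (disordered) carry only CA + CB and no carbonyl ladder, so
  # they stack into no intersheet contacts.
  zig <- 0.5
  cb_len <- 2.0
  o_len <- 1.7
  dx <- sqrt(ca_step^2 - (2 * zig)^2)
  chain_template <- function() {
    zz <- function(k) ifelse(k %% 2 == 0, zig, -zig)
    if (fold == "hairpin") {
      m <- ceiling(n / 2)
      k1 <- seq_len(m); k2 <- seq(m + 1, n)
      xs <- c((k1 - 1) * dx, (n - k2) * dx)
      ys <- c(zz(k1), arm_sep + zz(k2))
      # side-chain direction: into the arch for arm-facing residues,
      # outward within 2 residues of the turn
      sgn <- c(ifelse(zz(k1) > 0, 1, -1), ifelse(zz(k2) > 0, 1, -1))
      turn_zone <- abs(seq_len(n) - (m + 0.5)) <= 2.5
      sgn[turn_zone & seq_len(n) <= m] <- -1
      sgn[turn_zone & seq_len(n) > m] <- 1
    } else {
      xs <- (seq_len(n) - 1) * dx
      ys <- zz(seq_len(n))
      sgn <- ifelse(zz(seq_len(n)) > 0, 1, -1)
    }
    zs <- rep(0, n)
    if (n_tail > 0) {
      # disordered tail: drapes past the arch end at the arm-2 level; its side
      # groups point back toward the folded body, so the first tail residues
      # make a few weak, singly-coordinated contacts (the marginal anchoring
      # of disordered termini) while the rest stay contact-free
      x_end <- xs[n]; y_end <- arm_sep
      kt <- seq_len(n_tail)
      xs <- c(xs, x_end - kt * dx)
      ys <- c(ys, y_end + zz(n + kt))
      zs <- c(zs, rep(0, n_tail))
      sgn <- c(sgn, rep(-1, n_tail))
    }
    ntot <- n + n_tail
    ca <- cbind(xs, ys, zs)
    cb <- ca
    cb[, 2] <- cb[, 2] + sgn * cb_len
    ob <- ca[seq_len(n), , drop = FALSE]
    ob[, 3] <- ob[, 3] + o_len
    list(ca = ca, cb = cb, ob = ob, ntot = ntot)
  }

  tpl <- chain_template()
  chain_ids <- c(LETTERS, letters, as.character(0:9))
  n_chains <- n_layers * n_protofilaments
  if (n_chains > length(chain_ids)) stop("too many chains for PDB chain ids")

  rows <- vector("list", n_chains * tpl$ntot * 3)
  ri <- 0L
  ci <- 0L
  for (l in seq_len(n_layers) - 1L) {
    for (p in seq_len(n_protofilaments) - 1L) {
      ci <- ci + 1L
      off <- c(0, p * lateral_spacing, l * rise)
      for (k in seq_len(tpl$ntot)) {
        atoms_k <- if (k <= residues_per_chain) c("CA", "CB", "O") else c("CA", "CB")
        for (atom in atoms_k) {
          pos <- switch(atom, CA = tpl$ca[k, ], CB = tpl$cb[k, ],
                        O = tpl$ob[k, ]) + off
          ri <- ri + 1L
          rows[[ri]] <- data.frame(chain = chain_ids[ci], resno = k,
                                   resid = "ALA", elety = atom,
                                   elesy = if (atom == "O") "O" else "C",
                                   x = pos[1], y = pos[2], z = pos[3],
                                   insert = "", stringsAsFactors = FALSE)
        }
      }
    }
  }
  atoms <- do.call(rbind, rows[seq_len(ri)])

  # deterministic jitter, isolated from the caller's RNG stream
  jit <- .with_preserved_rng(seed, {
    matrix(stats::runif(nrow(atoms) * 3, -0.05, 0.05), ncol = 3)
  })
  atoms$x <- atoms$x + jit[, 1]
  atoms$y <- atoms$y + jit[, 2]
  atoms$z <- atoms$z + jit[, 3]

  .finish_structure(atoms, "synthetic")
}

# evaluate expr under set.seed(seed) without disturbing the caller's RNG
.with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  out <- force(expr)
  if (had) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
  out
}

#' Determine the fibril axis and stacking layers
#'
#' The axis is the principal eigenvector of the covariance of the per-chain
#' C-alpha centroids (each chain collapsed to its centroid, which isolates the
#' stacking direction from intra-chain spread); for a single chain the C-alpha
#' gyration eigenvector is used instead, with a warning. Chains are assigned
#' to stacking layers by 1-D gap clustering of their centroid projections on
#' the axis, and the axis is oriented so projections increase with layer index.
#'
#' @param structure a \code{fibril_structure}.
#' @param gap layer gap threshold, A; chains whose axial centroid projections
#'   differ by more than this fall in different layers. Default 2.4 (half a
#'   typical 4.8 A cross-beta rise).
#' @return Object of class \code{"fibril_frame"}: list with unit \code{axis},
#'   \code{origin} (overall C-alpha centroid), and \code{layer_of_chain}
#'   (named integer vector, contiguous from 0).
#' @export
fibril_frame <- function(structure, gap = 2.4) {
  ca <- calpha_coords(structure)
  res <- structure$residues
  origin <- colMeans(ca)
  cents <- t(vapply(structure$chains, function(ch)
    colMeans(ca[res$chain == ch, , drop = FALSE]), numeric(3)))
  if (structure$n_chains < 2) {
    warning("single chain: axis from C-alpha gyration tensor, layers = {0}")
    cc <- sweep(ca, 2, origin)
    ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
    axis <- ev$vectors[, 1]
    layers <- stats::setNames(0L, structure$chains)
  } else {
    cc <- sweep(cents, 2, colMeans(cents))
    ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
    axis <- ev$vectors[, 1]
    proj <- as.numeric(cents %*% axis)
    ord <- order(proj)
    lay <- integer(length(proj))
    lid <- 0L
    for (i in seq_along(ord)[-1]) {
      if (proj[ord[i]] - proj[ord[i - 1]] > gap) lid <- lid + 1L
      lay[ord[i]] <- lid
    }
    lay[ord[1]] <- 0L
    # orient axis so layer index increases with projection
    if (stats::var(lay) > 0 && stats::cor(proj, lay) < 0) {
      axis <- -axis
      lay <- max(lay) - lay
    }
    layers <- stats::setNames(lay, structure$chains)
  }
  axis <- axis / sqrt(sum(axis^2))
  structure(list(axis = as.numeric(axis), origin = as.numeric(origin),
                 layer_of_chain = layers),
            class = "fibril_frame")
}

#' @export
print.fibril_frame <- function(x, ...) {
  cat(sprintf("fibril_frame: axis = (%.3f, %.3f, %.3f), %d layer(s)\n",
              x$axis[1], x$axis[2], x$axis[3], max(x$layer_of_chain) + 1L))
  invisible(x)
}

#' Write C-alpha trajectory frames in XYZ format
#'
#' @param frames list of n x 3 coordinate matrices.
#' @param file output path.
#' @param labels atom labels (recycled), default "CA".
#' @return Invisibly, the path.
#' @export
write_xyz <- function(frames, file, labels = "CA") {
  con <- file(file, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr)
    lab <- rep_len(labels, n)
    writeLines(as.character(n), con)
    writeLines("fibrilmech frame", con)
    writeLines(sprintf("%s %12.5f %12.5f %12.5f", lab, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(file)
}
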