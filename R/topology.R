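#' Build bonded terms from the C-alpha trace
#'
#' Pseudo-bonds join consecutive residues of a chain, angles span three and
#' dihedrals four consecutive residues; equilibrium values are taken from the
#' native structure, so the native geometry is the minimum of every term.
#' Terms never span chain breaks.
#'
#' @param structure a \code{fibril_structure}.
#' @return List with data.frames \code{bonds} (i, j, r0), \code{angles}
#'   (i, j, k, theta0) and \code{dihedrals} (i, j, k, l, phi0); indices are
#'   bead numbers (1-based, chain-major residue order).
#' @export
build_bonded_terms <- function(structure) {
  ca <- calpha_coords(structure)
  res <- structure$residues
  bonds <- angles <- dihedrals <- NULL
  for (ch in structure$chains) {
    beads <- res$bead[res$chain == ch]
    nb <- length(beads)
    if (nb < 2) {
      warning("chain ", ch, " has fewer than 2 residues; no bonded terms")
      next
    }
    i <- beads[-nb]; j <- beads[-1]
    r0 <- sqrt(rowSums((ca[j, , drop = FALSE] - ca[i, , drop = FALSE])^2))
    bonds <- rbind(bonds, data.frame(i = i, j = j, r0 = r0))
    if (nb >= 3) {
      i <- beads[1:(nb - 2)]; j <- beads[2:(nb - 1)]; k <- beads[3:nb]
      th <- vapply(seq_along(i), function(m)
        .angle3(ca[i[m], ], ca[j[m], ], ca[k[m], ]), numeric(1))
      angles <- rbind(angles, data.frame(i = i, j = j, k = k, theta0 = th))
    }
    if (nb >= 4) {
      i <- beads[1:(nb - 3)]; j <- beads[2:(nb - 2)]
      k <- beads[3:(nb - 1)]; l <- beads[4:nb]
      ph <- vapply(seq_along(i), function(m)
        dihedral_angle(ca[i[m], ], ca[j[m], ], ca[k[m], ], ca[l[m], ]),
        numeric(1))
      dihedrals <- rbind(dihedrals, data.frame(i = i, j = j, k = k, l = l, phi0 = ph))
    }
  }
  empty <- function(cols) stats::setNames(
    data.frame(matrix(numeric(0), ncol = length(cols))), cols)
  list(bonds = if (is.null(bonds)) empty(c("i", "j", "r0")) else bonds,
       angles = if (is.null(angles)) empty(c("i", "j", "k", "theta0")) else angles,
       dihedrals = if (is.null(dihedrals)) empty(c("i", "j", "k", "l", "phi0")) else dihedrals)
}

.angle3 <- function(a, b, c) {
  u <- a - b; v <- c - b
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, ct)))
}

#' Dihedral angle of four points
#'
#' Signed torsion angle in (-pi, pi] about the axis p2-p3, matching the
#' convention of the force kernel.
#'
#' @param p1,p2,p3,p4 3-vectors.
#' @return Angle in radians.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  dihedral_angle_cpp(as.numeric(p1), as.numeric(p2), as.numeric(p3), as.numeric(p4))
}

#' Overlap criterion for a single atom pair
#'
#' Two heavy atoms overlap when their centre distance is strictly below the
#' sum of their van der Waals radii enlarged by the given factor.
#'
#' @param pos_a,pos_b atom positions (3-vectors, A).
#' @param radius_a,radius_b van der Waals radii (A).
#' @param enlargement enlargement factor (default 1.24).
#' @return Logical.
#' @export
overlap_contact <- function(pos_a, pos_b, radius_a, radius_b, enlargement = 1.24) {
  d <- sqrt(sum((pos_a - pos_b)^2))
  d < enlargement * (radius_a + radius_b)
}

#' Classify a contact as intrachain, interchain or intersheet
#'
#' Same chain: intrachain. Different chains in the same stacking layer
#' (side-by-side protofilaments): interchain. Different layers along the
#' fibril axis: intersheet.
#'
#' @param chain_i,chain_j chain identifiers.
#' @param frame a \code{fibril_frame} with layer assignments.
#' @return Character vector.
#' @export
classify_contact <- function(chain_i, chain_j, frame) {
  same_chain <- chain_i == chain_j
  li <- frame$layer_of_chain[chain_i]
  lj <- frame$layer_of_chain[chain_j]
  ifelse(same_chain, "intrachain",
         ifelse(li == lj, "interchain", "intersheet"))
}

#' Build the native contact map via the overlap criterion
#'
#' Every residue pair whose heavy atoms have overlapping enlarged van der
#' Waals spheres becomes a native contact between the two C-alpha beads, with
#' equilibrium distance \code{r0} equal to the native C-alpha separation and
#' \code{sigma = r0 / 2^(1/6)}. Pairs within one chain need a sequence
#' separation strictly greater than 4; pairs in different chains carry no
#' separation restriction. Each contact is stored once with \code{i < j}.
#'
#' @param structure a \code{fibril_structure}.
#' @param params a \code{model_params} (enlargement factor and radius table).
#' @param frame a \code{fibril_frame} used for classification; computed from
#'   the structure when missing.
#' @param prefilter C-alpha distance (A) beyond which residue pairs are not
#'   examined atom-by-atom; purely a speed device, conservative default 18.
#' @return data.frame with columns i, j (bead indices), r0, sigma, class.
#' @export
build_contact_map <- function(structure, params = model_params(),
                              frame = NULL, prefilter = 18) {
  if (is.null(frame)) frame <- fibril_frame(structure)
  ca <- calpha_coords(structure)
  res <- structure$residues
  at <- structure$atoms
  n <- nrow(res)
  rad <- atom_radius(at$elety, at$elesy, at$resid, params$radius_table)
  bead_of <- function(chain, ridx) res$bead[match(paste(chain, ridx),
                                                  paste(res$chain, res$ridx))]
  at_bead <- bead_of(at$chain, at$ridx)
  axyz <- as.matrix(at[, c("x", "y", "z")])
  atoms_by_bead <- split(seq_len(nrow(at)), at_bead)

  # residue-level prefilter on CA-CA distance
  d2 <- as.matrix(stats::dist(ca))^2
  cand <- which(upper.tri(d2) & d2 < prefilter^2, arr.ind = TRUE)
  out <- vector("list", nrow(cand))
  m <- 0L
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    same_chain <- res$chain[i] == res$chain[j]
    if (same_chain && abs(res$ridx[i] - res$ridx[j]) <= 4) next
    ai <- atoms_by_bead[[as.character(i)]]
    aj <- atoms_by_bead[[as.character(j)]]
    dd <- sqrt(pmax(outer(rowSums(axyz[ai, , drop = FALSE]^2),
                          rowSums(axyz[aj, , drop = FALSE]^2), "+") -
                    2 * axyz[ai, , drop = FALSE] %*% t(axyz[aj, , drop = FALSE]), 0))
    thr <- params$enlargement * outer(rad[ai], rad[aj], "+")
    if (any(dd < thr)) {
      m <- m + 1L
      out[[m]] <- c(i, j)
    }
  }
  if (m == 0L)
    return(data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                      sigma = numeric(0), class = character(0)))
  ij <- do.call(rbind, out[seq_len(m)])
  r0 <- sqrt(rowSums((ca[ij[, 1], , drop = FALSE] - ca[ij[, 2], , drop = FALSE])^2))
  cls <- classify_contact(res$chain[ij[, 1]], res$chain[ij[, 2]], frame)
  data.frame(i = ij[, 1], j = ij[, 2], r0 = r0, sigma = r0 / 2^(1 / 6),
             class = unname(cls), stringsAsFactors = FALSE)
}

#' Assemble the full Go-model topology of a structure
#'
#' Convenience constructor running \code{\link{build_bonded_terms}} and
#' \code{\link{build_contact_map}} and packaging the result for the energy and
#' dynamics routines.
#'
#' @inheritParams build_contact_map
#' @return Object of class \code{"fibril_topology"}: list with \code{bonds},
#'   \code{angles}, \code{dihedrals}, \code{contacts}, \code{n_beads},
#'   \code{chain_index} (integer chain id per bead), \code{frame} and
#'   \code{params}.
#' @export
build_topology <- function(structure, params = model_params(), frame = NULL) {
  if (is.null(frame)) frame <- fibril_frame(structure)
  bt <- build_bonded_terms(structure)
  contacts <- build_contact_map(structure, params, frame)
  res <- structure$residues
  structure(list(bonds = bt$bonds, angles = bt$angles, dihedrals = bt$dihedrals,
                 contacts = contacts, n_beads = nrow(res),
                 chain_index = as.integer(factor(res$chain,
                                                 levels = structure$chains)),
                 residues = res, frame = frame, params = params),
            class = "fibril_topology")
}

#' @export
print.fibril_topology <- function(x, ...) {
  tab <- table(factor(x$contacts$class,
                      levels = c("intrachain", "interchain", "intersheet")))
  cat(sprintf("fibril_topology: %d beads, %d bonds, %d angles, %d dihedrals\n",
              x$n_beads, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals)))
  cat(sprintf("  native contacts: %d (intrachain %d, interchain %d, intersheet %d)\n",
              nrow(x$contacts), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' @export
summary.fibril_topology <- function(object, ...) {
  cs <- object$contacts
  out <- list(n_beads = object$n_beads,
              n_bonds = nrow(object$bonds),
              n_angles = nrow(object$angles),
              n_dihedrals = nrow(object$dihedrals),
              n_contacts = nrow(cs),
              contacts_by_class = table(factor(cs$class,
                levels = c("intrachain", "interchain", "intersheet"))),
              mean_r0_by_class = tapply(cs$r0, cs$class, mean))
  class(out) <- "summary.fibril_topology"
  out
}

#' @export
print.summary.fibril_topology <- function(x, ...) {
  cat(sprintf("beads %d | bonds %d angles %d dihedrals %d | contacts %d\n",
              x$n_beads, x$n_bonds, x$n_angles, x$n_dihedrals, x$n_contacts))
  print(x$contacts_by_class)
  invisible(x)
}

#' Serialize a topology to JSON
#'
#' Schema: \code{n_beads}, \code{chain_index}, arrays \code{bonds}
#' (i, j, r0), \code{angles}, \code{dihedrals}, \code{contacts}
#' (i, j, r0, sigma, class), plus the scalar force-field constants.
#'
#' @param topology a \code{fibril_topology}.
#' @param file output path; when NULL the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
write_topology_json <- function(topology, file = NULL) {
  p <- topology$params
  obj <- list(n_beads = topology$n_beads,
              chain_index = topology$chain_index,
              bonds = topology$bonds, angles = topology$angles,
              dihedrals = topology$dihedrals, contacts = topology$contacts,
              params = list(K_r = p$K_r, K_theta = p$K_theta, K_phi = p$K_phi,
                            epsilon = p$epsilon, epsilon_rep = p$epsilon_rep,
                            r_cut = p$r_cut, enlargement = p$enlargement))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}

#' Export the contact map as a plain-text table
#'
#' Whitespace-separated columns: i, j, r0, class.
#'
#' @param topology a \code{fibril_topology}.
#' @param file output path.
#' @return Invisibly, the path.
#' @export
write_contact_table <- function(topology, file) {
  cs <- topology$contacts
  utils::write.table(cs[, c("i", "j", "r0", "class")], file,
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

# topology in the flat list layout the C++ kernels expect
.topo_for_cpp <- function(topology) {
  list(n_beads = topology$n_beads,
       chain_index = topology$chain_index,
       bonds = list(i = as.integer(topology$bonds$i),
                    j = as.integer(topology$bonds$j),
                    r0 = as.numeric(topology$bonds$r0)),
       angles = list(i = as.integer(topology$angles$i),
                     j = as.integer(topology$angles$j),
                     k = as.integer(topology$angles$k),
                     theta0 = as.numeric(topology$angles$theta0)),
       dihedrals = list(i = as.integer(topology$dihedrals$i),
                        j = as.integer(topology$dihedrals$j),
                        k = as.integer(topology$dihedrals$k),
                        l = as.integer(topology$dihedrals$l),
                        phi0 = as.numeric(topology$dihedrals$phi0)),
       contacts = list(i = as.integer(topology$contacts$i),
                       j = as.integer(topology$contacts$j),
                       sigma = as.numeric(topology$contacts$sigma)))
}

.params_for_cpp <- function(params) {
  list(K_r = params$K_r, K_theta = params$K_theta, K_phi = params$K_phi,
       epsilon = params$epsilon, epsilon_rep = params$epsilon_rep,
       r_cut = params$r_cut)
}
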