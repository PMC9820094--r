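# Coarse-grained membrane-plane geometry of a four-MPM transporter monomer
# (MPM = Membrane-helix - Pore-helix - Membrane-helix motif) and its symmetric
# dimer / tetramer arrangements.  All geometry is 2-D: every fusion-tag anchor
# (N-terminus, C-terminus, intracellular loop 3) is cytosolic, so the
# discriminating distances between anchors are lateral, in the membrane plane.
# Lengths are in arbitrary model units; the default unit is the nominal MPM
# diameter.

# Default anchor geometry.  Offsets displace each anchor from its home domain
# centre (N-terminus from MPM A, C-terminus from MPM D, loop 3 from the C-D
# edge midpoint); linker reaches are the maximum tether lengths of the fusion
# linkers plus the dangling fluorescent-protein fragment.  The numeric values
# were calibrated once (see the methods vignette) so that, with the default
# configuration, the computed feasibility table over the nine symmetric
# arrangements and five standard fusion experiments reproduces the verdicts
# established by atomic-scale structural modelling of the transporter.
.default_anchor_offsets <- function() {
  list(
    N_term = c(-0.54, 0.09),
    C_term = c(0.66, -1.25),
    loop3  = c(-1.38, 0.29)
  )
}

.default_linker_reach <- function() {
  c(N_term = 1.34, C_term = 1.74, loop3 = 0.91)
}

#' Build a coarse-grained monomer layout
#'
#' Places the four MPM domains (A-D) of one transporter monomer as disks in
#' the membrane plane, arranged counter-clockwise around a central pore
#' (viewed from the extracellular side), and attaches cytosolic fusion-tag
#' anchors: the N-terminus homed at MPM A, the C-terminus at MPM D, and the
#' loop-3 insertion point at the C-D edge midpoint.
#'
#' @param domain_radius Radius of each MPM disk (model units).
#' @param domain_spacing Centre-to-centre distance of adjacent MPM domains;
#'   the four centres sit at the corners of a square of this side length,
#'   centred on the pore at the origin.
#' @param anchor_offsets Named list of 2-D offsets (`N_term`, `C_term`,
#'   `loop3`) from each anchor's home position.  Defaults are calibrated; see
#'   Details.
#' @param linker_reach Named numeric vector of maximum tether lengths per
#'   anchor kind.  All must be strictly positive.
#'
#' @details The centroid of the four domain centres is the pore centre at the
#'   origin; domains are ordered A, B, C, D counter-clockwise.  Default
#'   radius and spacing make adjacent domain disks touch.
#'
#' @return An object of class `monomer_layout` with elements
#'   `domain_centers` (4 x 2 matrix, rows A-D), `domain_radius`,
#'   `anchor_offsets`, `anchor_home`, `linker_reach`.
#' @export
#' @examples
#' lay <- monomer_layout()
#' colMeans(lay$domain_centers)  # pore centre (0, 0)
monomer_layout <- function(domain_radius = 0.5,
                           domain_spacing = 1,
                           anchor_offsets = .default_anchor_offsets(),
                           linker_reach = .default_linker_reach()) {
  check_positive_scalar(domain_radius, "domain_radius")
  check_positive_scalar(domain_spacing, "domain_spacing")
  kinds <- c("N_term", "C_term", "loop3")
  if (!all(kinds %in% names(anchor_offsets))) {
    stop_param("`anchor_offsets` must name all of: %s", paste(kinds, collapse = ", "))
  }
  if (!all(kinds %in% names(linker_reach))) {
    stop_param("`linker_reach` must name all of: %s", paste(kinds, collapse = ", "))
  }
  for (k in kinds) check_positive_scalar(unname(linker_reach[[k]]), paste0("linker_reach[", k, "]"))

  h <- domain_spacing / 2
  centers <- rbind(
    A = c(h, h),
    B = c(-h, h),
    C = c(-h, -h),
    D = c(h, -h)
  )
  structure(
    list(
      domain_centers = centers,
      domain_radius = domain_radius,
      domain_spacing = domain_spacing,
      anchor_home = list(N_term = "A", C_term = "D", loop3 = c("C", "D")),
      anchor_offsets = lapply(anchor_offsets[kinds], as.numeric),
      linker_reach = vapply(kinds, function(k) as.numeric(linker_reach[[k]]), numeric(1))
    ),
    class = "monomer_layout"
  )
}

#' @export
print.monomer_layout <- function(x, ...) {
  cat("<monomer_layout> 4 MPM domains, radius", format(x$domain_radius),
      ", spacing", format(x$domain_spacing), "\n")
  print(round(x$domain_centers, 3))
  cat("anchors:", paste(names(x$anchor_offsets), collapse = ", "), "\n")
  invisible(x)
}

# Anchor position within the monomer frame (before any pose is applied).
anchor_local <- function(layout, kind) {
  home <- layout$anchor_home[[kind]]
  if (is.null(home)) stop_param("unknown anchor kind '%s'", kind)
  base <- colMeans(layout$domain_centers[home, , drop = FALSE])
  base + layout$anchor_offsets[[kind]]
}

#' Cyclically relabel the MPM domains of a layout
#'
#' Shifts every domain label one step along A -> B -> C -> D -> A (or the
#' reverse), keeping coordinates fixed.  Anchors stay homed at their label
#' (N-terminus at "A", ...), so their positions move with the relabelling.
#' Used to test relabelling equivariance of interface predictions.
#'
#' @param layout A `monomer_layout`.
#' @param shift Integer label shift: every domain keeps its position but its
#'   label advances by `shift` letters (with `shift = -1`, the domain at the
#'   old D position is called C, the one at the old A position is called D,
#'   and so on).
#' @return A relabelled `monomer_layout`.
#'
#' @details All geometry (domain positions, anchor positions) is unchanged;
#'   only the labels move, and anchor homes are relabelled with their
#'   domains.  Interface predictions are therefore equivariant under
#'   relabelling: with `shift = -1`, the CD-interface distances of the
#'   relabelled layout equal the DA-interface distances of the original.
#' @export
relabel_layout <- function(layout, shift = 1L) {
  stopifnot(inherits(layout, "monomer_layout"))
  labs <- c("A", "B", "C", "D")
  shift <- as.integer(shift)
  pi_map <- function(l) labs[((match(l, labs) - 1L + shift) %% 4L) + 1L]
  new <- layout
  centers <- layout$domain_centers
  rownames(centers) <- pi_map(rownames(centers))
  new$domain_centers <- centers[labs, , drop = FALSE]
  new$anchor_home <- lapply(layout$anchor_home, pi_map)
  new
}

.dimer_interfaces <- c("AB", "BC", "CD", "DA")
.tetramer_centers <- c("A", "B", "C", "D")

#' Enumerate the standard symmetric arrangements
#'
#' The monomer, the four symmetric (C2) dimers named by their MPM-MPM
#' interface, and the four symmetric (C4) tetramers named by their central
#' MPM.
#'
#' @param layout A `monomer_layout` shared by all arrangements.
#' @return Named list of nine `arrangement` objects.
#' @export
standard_arrangements <- function(layout = monomer_layout()) {
  ids <- c("monomer",
           paste0("dimer_", .dimer_interfaces),
           paste0("tetramer_", .tetramer_centers))
  out <- c(
    list(build_arrangement("monomer", layout = layout)),
    lapply(.dimer_interfaces, build_arrangement, kind = "dimer", layout = layout),
    lapply(.tetramer_centers, build_arrangement, kind = "tetramer", layout = layout)
  )
  names(out) <- ids
  out
}

#' Build a symmetric oligomer arrangement
#'
#' Constructs the rigid poses of 1, 2 or 4 copies of a monomer layout:
#' a monomer (identity pose), a C2 dimer whose interface is a named MPM edge
#' (`"AB"`, `"BC"`, `"CD"`, `"DA"`), or a C4 tetramer whose four copies of a
#' named central MPM (`"A"`-`"D"`) surround the global centroid.
#'
#' @param kind One of `"monomer"`, `"dimer"`, `"tetramer"`.
#' @param spec Interface label for dimers, central MPM for tetramers, `NULL`
#'   for the monomer.
#' @param layout A `monomer_layout`.
#' @param contact_gap Extra separation between abutting domain disks
#'   (default 0: contact without interpenetration).
#' @return An object of class `arrangement` with elements `id`, `kind`,
#'   `spec`, `layout` and `poses` (list of `list(angle, shift)`).
#' @export
#' @examples
#' arr <- build_arrangement("dimer", "CD")
#' arrangement_domains(arr)
build_arrangement <- function(kind = c("monomer", "dimer", "tetramer"),
                              spec = NULL,
                              layout = monomer_layout(),
                              contact_gap = 0) {
  kind <- match.arg(kind)
  stopifnot(inherits(layout, "monomer_layout"))
  check_nonneg_scalar(contact_gap, "contact_gap")
  r <- layout$domain_radius

  if (kind == "monomer") {
    if (!is.null(spec)) stop_param("`spec` must be NULL for a monomer")
    poses <- list(list(angle = 0, shift = c(0, 0)))
    id <- "monomer"
  } else if (kind == "dimer") {
    if (is.null(spec) || !spec %in% .dimer_interfaces) {
      stop_param("dimer `spec` must be one of: %s", paste(.dimer_interfaces, collapse = ", "))
    }
    d1 <- substr(spec, 1, 1); d2 <- substr(spec, 2, 2)
    m <- colMeans(layout$domain_centers[c(d1, d2), ])
    n_hat <- m / sqrt(sum(m^2))  # outward normal of the interface edge
    q <- m + (r + contact_gap / 2) * n_hat
    # C2 rotation about q:  p -> 2q - p
    poses <- list(
      list(angle = 0, shift = c(0, 0)),
      list(angle = pi, shift = 2 * q)
    )
    id <- paste0("dimer_", spec)
  } else {
    if (is.null(spec) || !spec %in% .tetramer_centers) {
      stop_param("tetramer `spec` must be one of: %s", paste(.tetramer_centers, collapse = ", "))
    }
    v <- layout$domain_centers[spec, ]
    rv <- sqrt(sum(v^2))
    phi <- atan2(v[2], v[1])
    alpha <- pi - phi                  # central MPM points towards the origin
    a <- sqrt(2) * r + contact_gap     # distance of the central MPM copies
    t0 <- c(a + rv, 0)
    poses <- lapply(0:3, function(k) {
      th <- k * pi / 2
      list(angle = th + alpha, shift = as.numeric(rot2(th) %*% t0))
    })
    id <- paste0("tetramer_", spec)
  }

  structure(
    list(id = id, kind = kind, spec = spec, layout = layout, poses = poses),
    class = "arrangement"
  )
}

#' @export
print.arrangement <- function(x, ...) {
  cat("<arrangement>", x$id, "-", length(x$poses), "monomer(s)\n")
  invisible(x)
}

#' Domain-disk coordinates of an arrangement
#'
#' @param arrangement An `arrangement`.
#' @return `data.frame` with columns `monomer`, `domain`, `x`, `y`.
#' @export
arrangement_domains <- function(arrangement) {
  stopifnot(inherits(arrangement, "arrangement"))
  lay <- arrangement$layout
  out <- lapply(seq_along(arrangement$poses), function(i) {
    xy <- apply_pose(lay$domain_centers, arrangement$poses[[i]])
    data.frame(monomer = i, domain = rownames(lay$domain_centers),
               x = xy[, 1], y = xy[, 2], row.names = NULL)
  })
  do.call(rbind, out)
}

# Anchor position of `kind` on monomer `i` of an arrangement.
anchor_position <- function(arrangement, monomer, kind) {
  local <- anchor_local(arrangement$layout, kind)
  as.numeric(apply_pose(matrix(local, 1L), arrangement$poses[[monomer]]))
}

# Cross-monomer domain-disk interpenetration (most negative clearance).
max_domain_overlap <- function(arrangement) {
  dd <- arrangement_domains(arrangement)
  n <- nrow(dd)
  if (length(arrangement$poses) < 2L) return(0)
  d <- as.matrix(stats::dist(dd[, c("x", "y")]))
  same <- outer(dd$monomer, dd$monomer, "==")
  cross <- d[!same]
  max(0, 2 * arrangement$layout$domain_radius - min(cross))
}
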