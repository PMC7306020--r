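#' Tetrahedral mesh container
#'
#' @param nodes Numeric matrix (n x 3) of node coordinates in mm.
#' @param tets Integer matrix (m x 4) of 1-based node indices, one row per
#'   four-node tetrahedron. No index may repeat within an element.
#' @return Object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets) {
  nodes <- as.matrix(nodes)
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stop("'nodes' must have 3 columns (x, y, z in mm)")
  if (ncol(tets) != 4L) stop("'tets' must have 4 columns (node indices)")
  if (nrow(tets) > 0L) {
    if (min(tets) < 1L || max(tets) > nrow(nodes))
      stop("tet node indices out of range")
    if (any(apply(tets, 1L, function(r) anyDuplicated(r) > 0L)))
      stop("a tetrahedron repeats a node index (degenerate connectivity)")
  }
  structure(list(nodes = nodes, tets = tets), class = "tet_mesh")
}

tet_vertices <- function(mesh, e) mesh$nodes[mesh$tets[e, ], , drop = FALSE]

# the 6 vertex-index pairs forming tet edges, and the opposite pairs
tet_edge_pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))

#' Tetrahedron aspect ratio
#'
#' Longest edge length divided by the smallest of the four vertex-to-opposite-
#' face altitudes. The regular tetrahedron is the minimizer with
#' AR = sqrt(3/2) ~ 1.2247; a coplanar (zero-volume) element scores +Inf
#' rather than raising, so audits never abort on degenerate elements.
#'
#' @param verts 4 x 3 numeric matrix of vertex coordinates.
#' @return Dimensionless aspect ratio (>= sqrt(3/2) for non-degenerate tets).
#' @export
aspect_ratio <- function(verts) {
  verts <- as.matrix(verts)
  stopifnot(nrow(verts) == 4L, ncol(verts) == 3L)
  d <- as.matrix(stats::dist(verts))
  edges <- d[lower.tri(d)]
  if (any(edges == 0)) stop("duplicated vertices: not a tetrahedron")
  vol6 <- abs(det(rbind(verts[2, ] - verts[1, ],
                        verts[3, ] - verts[1, ],
                        verts[4, ] - verts[1, ])))
  if (vol6 == 0) return(Inf)
  # altitude from vertex i = 3V / area(opposite face)
  altitudes <- vapply(1:4, function(i) {
    f <- verts[-i, , drop = FALSE]
    area <- 0.5 * sqrt(sum(crossprod3(f[2, ] - f[1, ], f[3, ] - f[1, ])^2))
    (vol6 / 6) * 3 / area
  }, numeric(1))
  max(edges) / min(altitudes)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angles of a tetrahedron
#'
#' Interior angle between the two faces meeting along each of the 6 edges,
#' in degrees, each in (0, 180). For the regular tetrahedron all six equal
#' acos(1/3) ~ 70.529 deg.
#'
#' @param verts 4 x 3 numeric matrix of vertex coordinates.
#' @return Numeric vector of 6 angles (degrees), ordered by edge
#'   (1-2, 1-3, 1-4, 2-3, 2-4, 3-4).
#' @export
dihedral_angles <- function(verts) {
  verts <- as.matrix(verts)
  stopifnot(nrow(verts) == 4L, ncol(verts) == 3L)
  vol6 <- det(rbind(verts[2, ] - verts[1, ],
                    verts[3, ] - verts[1, ],
                    verts[4, ] - verts[1, ]))
  if (vol6 == 0) stop("coplanar vertices: dihedral angles undefined")
  apply(tet_edge_pairs, 1L, function(pr) {
    other <- setdiff(1:4, pr)
    b <- verts[pr[2], ] - verts[pr[1], ]
    b <- b / sqrt(sum(b^2))
    # components of the two off-edge vertices orthogonal to the edge
    v1 <- verts[other[1], ] - verts[pr[1], ]
    v2 <- verts[other[2], ] - verts[pr[1], ]
    v1 <- v1 - sum(v1 * b) * b
    v2 <- v2 - sum(v2 * b) * b
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  })
}

# corner vertex orderings whose outgoing-edge determinant equals +6V for a
# positively oriented tet
tet_corner_order <- list(c(1, 2, 3, 4), c(2, 1, 4, 3), c(3, 1, 2, 4), c(4, 1, 3, 2))

#' Scaled Jacobian of a tetrahedron
#'
#' Minimum over the four corners of
#' `det(e1, e2, e3) * sqrt(2) / (|e1| |e2| |e3|)`, where `e1..e3` are the
#' corner's outgoing edge vectors taken in orientation-consistent order. The
#' sqrt(2) normalization makes the positively oriented regular tetrahedron
#' score exactly 1; coplanar elements score 0 and inverted elements are
#' negative. Range (-1, 1] for valid input; never raises.
#'
#' @param verts 4 x 3 numeric matrix of vertex coordinates.
#' @return Signed dimensionless quality in (-sqrt(2), sqrt(2)) numerically,
#'   within (-1, 1] for real tets.
#' @export
scaled_jacobian <- function(verts) {
  verts <- as.matrix(verts)
  stopifnot(nrow(verts) == 4L, ncol(verts) == 3L)
  vals <- vapply(tet_corner_order, function(ord) {
    e1 <- verts[ord[2], ] - verts[ord[1], ]
    e2 <- verts[ord[3], ] - verts[ord[1], ]
    e3 <- verts[ord[4], ] - verts[ord[1], ]
    len <- sqrt(sum(e1^2)) * sqrt(sum(e2^2)) * sqrt(sum(e3^2))
    if (len == 0) return(0)
    det(rbind(e1, e2, e3)) * sqrt(2) / len
  }, numeric(1))
  min(vals)
}

#' Audit a tetrahedral mesh against element-quality acceptance criteria
#'
#' Computes per-element aspect ratio, dihedral-angle range, edge-length range
#' and scaled Jacobian, then applies the acceptance criteria used for
#' childbirth-simulation meshes:
#' \itemize{
#'   \item fewer than 5\% of elements with aspect ratio > 3;
#'   \item all dihedral angles within \[30, 120\] degrees;
#'   \item all edge lengths within \[1, 3\] mm;
#'   \item all scaled Jacobians positive, none below 0.2 in magnitude, and
#'     fewer than 5\% below 0.7.
#' }
#' All percentages are exact rational counts over the element number, so the
#' pass/fail logic carries no float drift.
#'
#' @param mesh A [tet_mesh()] with at least one element.
#' @param criteria Optional overrides, a list with any of `ar_max` (3),
#'   `ar_pct_max` (5), `dihedral_min_deg` (30), `dihedral_max_deg` (120),
#'   `edge_min_mm` (1), `edge_max_mm` (3), `jacobian_min` (0.2),
#'   `jacobian_soft` (0.7), `jacobian_soft_pct_max` (5).
#' @return Object of class `mesh_quality_report`: per-element data frame
#'   `elements` plus aggregate fields `pct_ar_gt_3`, `pct_jacobian_below_0_7`,
#'   `any_nonpositive_jacobian`, `any_jacobian_below_0_2`,
#'   `any_dihedral_outside_30_120`, `any_edge_outside_1_3mm`,
#'   `passes_criteria`, `criteria`.
#' @export
audit_mesh <- function(mesh, criteria = list()) {
  stopifnot(inherits(mesh, "tet_mesh"))
  m <- nrow(mesh$tets)
  if (m == 0L) stop("mesh has no elements to audit")
  crit <- utils::modifyList(list(
    ar_max = 3, ar_pct_max = 5,
    dihedral_min_deg = 30, dihedral_max_deg = 120,
    edge_min_mm = 1, edge_max_mm = 3,
    jacobian_min = 0.2, jacobian_soft = 0.7, jacobian_soft_pct_max = 5
  ), criteria)

  rows <- lapply(seq_len(m), function(e) {
    v <- tet_vertices(mesh, e)
    d <- as.matrix(stats::dist(v))
    edges <- d[lower.tri(d)]
    sj <- scaled_jacobian(v)
    ang <- if (sj != 0) dihedral_angles(v) else c(NA_real_, NA_real_)
    data.frame(element_id = e,
               aspect_ratio = aspect_ratio(v),
               min_dihedral_deg = suppressWarnings(min(ang)),
               max_dihedral_deg = suppressWarnings(max(ang)),
               min_edge_mm = min(edges), max_edge_mm = max(edges),
               scaled_jacobian = sj)
  })
  el <- do.call(rbind, rows)

  n_ar <- sum(el$aspect_ratio > crit$ar_max)
  n_jac_soft <- sum(abs(el$scaled_jacobian) < crit$jacobian_soft)
  rep <- list(
    elements = el,
    n_elements = m,
    pct_ar_gt_3 = 100 * n_ar / m,
    pct_jacobian_below_0_7 = 100 * n_jac_soft / m,
    any_nonpositive_jacobian = any(el$scaled_jacobian <= 0),
    any_jacobian_below_0_2 = any(abs(el$scaled_jacobian) < crit$jacobian_min),
    any_dihedral_outside_30_120 = any(
      is.na(el$min_dihedral_deg) |
        el$min_dihedral_deg < crit$dihedral_min_deg |
        el$max_dihedral_deg > crit$dihedral_max_deg),
    any_edge_outside_1_3mm = any(el$min_edge_mm < crit$edge_min_mm |
                                   el$max_edge_mm > crit$edge_max_mm),
    criteria = crit
  )
  rep$passes_criteria <-
    (n_ar * 100 < crit$ar_pct_max * m) &&
    !rep$any_nonpositive_jacobian &&
    !rep$any_jacobian_below_0_2 &&
    (n_jac_soft * 100 < crit$jacobian_soft_pct_max * m) &&
    !rep$any_dihedral_outside_30_120 &&
    !rep$any_edge_outside_1_3mm
  structure(rep, class = "mesh_quality_report")
}

#' @export
print.mesh_quality_report <- function(x, ...) {
  cat(sprintf("Mesh quality report: %d tetrahedra\n", x$n_elements))
  cat(sprintf("  AR > %g: %.4g%% (limit < %g%%)\n",
              x$criteria$ar_max, x$pct_ar_gt_3, x$criteria$ar_pct_max))
  cat(sprintf("  scaled Jacobian < %g: %.4g%% (limit < %g%%); nonpositive: %s; < %g: %s\n",
              x$criteria$jacobian_soft, x$pct_jacobian_below_0_7,
              x$criteria$jacobian_soft_pct_max, x$any_nonpositive_jacobian,
              x$criteria$jacobian_min, x$any_jacobian_below_0_2))
  cat(sprintf("  dihedral outside [%g, %g] deg: %s; edge outside [%g, %g] mm: %s\n",
              x$criteria$dihedral_min_deg, x$criteria$dihedral_max_deg,
              x$any_dihedral_outside_30_120,
              x$criteria$edge_min_mm, x$criteria$edge_max_mm,
              x$any_edge_outside_1_3mm))
  cat(sprintf("  PASSES criteria: %s\n", x$passes_criteria))
  invisible(x)
}

#' Write a mesh quality report
#'
#' Writes the aggregate report as JSON and the per-element metrics as CSV
#' (`element_id,aspect_ratio,min_dihedral_deg,max_dihedral_deg,min_edge_mm,
#' max_edge_mm,scaled_jacobian`).
#'
#' @param report A [audit_mesh()] report.
#' @param json_path,csv_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, a list of the paths written.
#' @export
write_quality_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "mesh_quality_report"))
  if (!is.null(json_path)) {
    agg <- report[setdiff(names(report), "elements")]
    jsonlite::write_json(agg, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path))
    utils::write.csv(report$elements, csv_path, row.names = FALSE)
  invisible(list(json = json_path, csv = csv_path))
}

#' Read a tetrahedral mesh from a standard ASCII format
#'
#' Supports legacy ASCII VTK unstructured grids (`DATASET UNSTRUCTURED_GRID`
#' with `CELL_TYPES` all 10) and Gmsh MSH 2.2 ASCII (`$MeshFormat 2.2`,
#' element type 4). Meshes containing any other cell type are rejected with
#' a clear error: the audit is defined for four-node tetrahedra only.
#'
#' @param path Mesh file path; format is chosen by extension (`.vtk`,
#'   `.msh`) unless `format` is given.
#' @param format `"vtk"`, `"msh"` or `NULL` (from extension).
#' @return A [tet_mesh()].
#' @export
read_tet_mesh <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     vtk = "vtk", msh = "msh",
                     stop("cannot infer mesh format from extension; pass 'format'"))
  }
  switch(format, vtk = read_vtk_tets(path), msh = read_msh_tets(path),
         stop("unsupported mesh format: ", format))
}

read_vtk_tets <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("UNSTRUCTURED_GRID", lines)))
    stop("not a legacy VTK unstructured grid: ", path)
  toks <- scan(text = paste(lines, collapse = "\n"), what = "character",
               quiet = TRUE)
  ip <- which(toupper(toks) == "POINTS")[1]
  if (is.na(ip)) stop("VTK file has no POINTS section")
  np <- as.integer(toks[ip + 1])
  coords <- as.numeric(toks[(ip + 3):(ip + 2 + 3 * np)])
  nodes <- matrix(coords, ncol = 3, byrow = TRUE)
  ic <- which(toupper(toks) == "CELLS")[1]
  if (is.na(ic)) stop("VTK file has no CELLS section")
  nc <- as.integer(toks[ic + 1])
  sz <- as.integer(toks[ic + 2])
  cell_data <- as.integer(toks[(ic + 3):(ic + 2 + sz)])
  it <- which(toupper(toks) == "CELL_TYPES")[1]
  if (is.na(it)) stop("VTK file has no CELL_TYPES section")
  types <- as.integer(toks[(it + 2):(it + 1 + nc)])
  if (any(types != 10L))
    stop("mesh contains non-tetrahedral cells (VTK type != 10); only tet4 meshes are supported")
  tets <- matrix(NA_integer_, nrow = nc, ncol = 4)
  pos <- 1L
  for (e in seq_len(nc)) {
    cnt <- cell_data[pos]
    if (cnt != 4L) stop("VTK tet cell with ", cnt, " nodes")
    tets[e, ] <- cell_data[(pos + 1L):(pos + 4L)] + 1L  # VTK is 0-based
    pos <- pos + cnt + 1L
  }
  tet_mesh(nodes, tets)
}

read_msh_tets <- function(path) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- which(lines == paste0("$", name))
    i1 <- which(lines == paste0("$End", name))
    if (length(i0) != 1L || length(i1) != 1L)
      stop("malformed MSH file: missing $", name, " section")
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(trimws(sect("MeshFormat")[1]), "\\s+")[[1]]
  if (!startsWith(fmt[1], "2"))
    stop("only Gmsh MSH 2.x ASCII is supported (got version ", fmt[1], ")")
  nb <- sect("Nodes")
  nn <- as.integer(nb[1])
  nodetab <- do.call(rbind, lapply(nb[-1], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  nodes <- matrix(NA_real_, nrow = nn, ncol = 3)
  # MSH node ids may be non-contiguous; remap to 1..nn
  ids <- as.integer(nodetab[, 1])
  remap <- integer(max(ids)); remap[ids] <- seq_len(nn)
  nodes[remap[ids], ] <- nodetab[, 2:4]
  eb <- sect("Elements")
  ne <- as.integer(eb[1])
  tets <- matrix(NA_integer_, nrow = 0, ncol = 4)
  rows <- lapply(eb[-1], function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  types <- vapply(rows, function(r) r[2], integer(1))
  if (any(!types %in% c(4L, 15L, 1L, 2L)))
    stop("mesh contains unsupported element types; only tet4 (and point/line/tri markers) handled")
  tet_rows <- rows[types == 4L]
  if (length(tet_rows) == 0L) stop("MSH file contains no tetrahedra")
  if (any(types %in% c(15L, 1L, 2L)) && length(tet_rows) != ne)
    types <- types  # lower-dim boundary entities are silently ignored
  tets <- do.call(rbind, lapply(tet_rows, function(r) {
    ntags <- r[3]
    remap[r[(4 + ntags):(7 + ntags)]]
  }))
  tet_mesh(nodes, tets)
}

#' Write a tetrahedral mesh as legacy ASCII VTK
#'
#' @param mesh A [tet_mesh()].
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_tets <- function(mesh, path) {
  stopifnot(inherits(mesh, "tet_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  invisible(path)
}
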