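#' @name rsml
#' @title RSML root trace input/output
#'
#' @description
#' Root System Markup Language (RSML) is the XML interchange format
#' emitted by root tracing tools. A document holds a scene of plants,
#' each plant a hierarchy of \code{<root>} elements whose geometry is a
#' polyline of 3D points; per-node radii and creation times travel as
#' RSML "functions" attached to the polyline. Readers here accept both
#' per-node diameter/radius function arrays and a single root-level
#' radius attribute; the writer always emits per-node radii.
#'
#' A root trace is represented as a plain list with fields \code{id},
#' \code{parent_id} (NULL for top-level roots), \code{polyline} (n x 3
#' matrix, cm, z negative downward), \code{radius} (per-node, cm),
#' \code{ctime} (per-node creation times in days, or NULL when the file
#' carried none) and \code{type} (one of primary, seminal, crown,
#' l-lateral, s-lateral, unlabelled).
NULL

#' Construct a validated RSML root record
#'
#' @param id root identifier (character).
#' @param polyline numeric n x 3 matrix of points (cm), n >= 2.
#' @param radius per-node radii (cm), positive; recycled if scalar.
#' @param type root type label.
#' @param parent_id id of the parent root, or NULL.
#' @param ctime per-node creation times (days), or NULL.
#' @return list of class \code{rsml_root}.
#' @export
rsml_root <- function(id, polyline, radius, type = "unlabelled",
                      parent_id = NULL, ctime = NULL) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) {
    stop(sprintf("root '%s' has fewer than 2 nodes", id))
  }
  if (ncol(polyline) != 3) stop("polyline must have 3 columns (x, y, z)")
  radius <- rep_len(radius, nrow(polyline))
  if (any(radius <= 0)) stop(sprintf("root '%s' has non-positive radii", id))
  if (!is.null(ctime) && length(ctime) != nrow(polyline)) {
    stop("ctime must have one value per node")
  }
  structure(list(id = as.character(id), parent_id = parent_id,
                 polyline = unname(polyline), radius = radius,
                 ctime = ctime, type = type),
            class = "rsml_root")
}

.num_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NA_real_ else as.numeric(v)
}

.read_function_values <- function(root_node, names_wanted) {
  fns <- xml2::xml_find_all(root_node, "./functions/function")
  for (fn in fns) {
    nm <- xml2::xml_attr(fn, "name")
    if (!is.na(nm) && nm %in% names_wanted) {
      smp <- xml2::xml_find_all(fn, "./sample")
      return(list(name = nm,
                  values = as.numeric(xml2::xml_attr(smp, "value"))))
    }
  }
  NULL
}

.parse_root_node <- function(node, parent_id, order, first_at_order0) {
  id <- xml2::xml_attr(node, "ID")
  if (is.na(id)) id <- xml2::xml_attr(node, "id")
  if (is.na(id)) id <- paste0("root_", order, "_", sample.int(1e6, 1))
  pts <- xml2::xml_find_all(node, "./geometry/polyline/point")
  if (length(pts) < 2) {
    stop(sprintf("root '%s' rejected: polyline has %d node(s), need >= 2",
                 id, length(pts)))
  }
  poly <- cbind(as.numeric(xml2::xml_attr(pts, "x")),
                as.numeric(xml2::xml_attr(pts, "y")),
                as.numeric(xml2::xml_attr(pts, "z")))
  dia <- .read_function_values(node, c("diameter"))
  rad <- .read_function_values(node, c("radius"))
  if (!is.null(rad)) {
    radius <- rad$values
  } else if (!is.null(dia)) {
    radius <- dia$values / 2
  } else {
    r_attr <- .num_attr(node, "radius")
    d_attr <- .num_attr(node, "diameter")
    radius <- if (!is.na(r_attr)) r_attr else if (!is.na(d_attr)) {
      d_attr / 2
    } else {
      stop(sprintf("root '%s' carries no radius information", id))
    }
  }
  ct <- .read_function_values(
    node, c("creation_time", "emergence_time", "node_creation_time", "age"))
  label <- xml2::xml_attr(node, "label")
  if (is.na(label) || !nzchar(label)) {
    # default typing by branching order: order 0 -> axial, deeper -> lateral
    label <- if (order == 0) {
      if (first_at_order0) "primary" else "crown"
    } else "l-lateral"
  }
  rsml_root(id = id, polyline = poly, radius = radius, type = label,
            parent_id = parent_id,
            ctime = if (is.null(ct)) NULL else ct$values)
}

#' Read an RSML file
#'
#' Parses the scene/plant/root hierarchy, preserving parent-child links
#' and type labels. Creation times are returned only when present in the
#' file (attribute \code{time_source} on the result records the function
#' name they came from, or "none"); they are never invented.
#'
#' @param path path to an RSML (XML) file.
#' @return list of \code{rsml_root} records.
#' @export
read_rsml <- function(path) {
  doc <- xml2::read_xml(path)
  out <- list()
  time_source <- "none"
  walk <- function(node, parent_id, order, first) {
    r <- .parse_root_node(node, parent_id, order, first)
    out[[length(out) + 1]] <<- r
    ct <- .read_function_values(
      node, c("creation_time", "emergence_time", "node_creation_time", "age"))
    if (!is.null(ct)) time_source <<- ct$name
    kids <- xml2::xml_find_all(node, "./root")
    for (k in seq_along(kids)) {
      walk(kids[[k]], r$id, order + 1, first = FALSE)
    }
  }
  plants <- xml2::xml_find_all(doc, ".//scene/plant")
  for (pl in plants) {
    tops <- xml2::xml_find_all(pl, "./root")
    for (i in seq_along(tops)) {
      walk(tops[[i]], NULL, 0, first = (i == 1))
    }
  }
  attr(out, "time_source") <- time_source
  out
}

.fmt <- function(x) sprintf("%.10f", x)

.write_root_node <- function(parent_node, root, children_of) {
  rn <- xml2::xml_add_child(parent_node, "root", ID = root$id,
                            label = root$type)
  geom <- xml2::xml_add_child(rn, "geometry")
  poly <- xml2::xml_add_child(geom, "polyline")
  for (i in seq_len(nrow(root$polyline))) {
    xml2::xml_add_child(poly, "point",
                        x = .fmt(root$polyline[i, 1]),
                        y = .fmt(root$polyline[i, 2]),
                        z = .fmt(root$polyline[i, 3]))
  }
  fns <- xml2::xml_add_child(rn, "functions")
  fd <- xml2::xml_add_child(fns, "function", name = "diameter",
                            domain = "polyline")
  for (v in root$radius * 2) {
    xml2::xml_add_child(fd, "sample", value = .fmt(v))
  }
  if (!is.null(root$ctime)) {
    ft <- xml2::xml_add_child(fns, "function", name = "creation_time",
                              domain = "polyline")
    for (v in root$ctime) {
      xml2::xml_add_child(ft, "sample", value = .fmt(v))
    }
  }
  for (ch in children_of[[root$id]]) {
    .write_root_node(rn, ch, children_of)
  }
}

#' Write roots to an RSML file
#'
#' Emits a single-scene, single-plant RSML document with nested
#' \code{<root>} elements following the parent links, per-node diameter
#' samples and (when available) per-node creation times. Reading the file
#' back reproduces topology and labels exactly and coordinates to within
#' 1e-9 cm.
#'
#' @param roots list of \code{rsml_root} records (may be empty).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_rsml <- function(roots, path) {
  ids <- vapply(roots, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate root ids")
  children_of <- list()
  tops <- list()
  for (r in roots) {
    if (is.null(r$parent_id)) {
      tops[[length(tops) + 1]] <- r
    } else {
      if (!r$parent_id %in% ids) {
        stop(sprintf("root '%s' references unknown parent '%s'",
                     r$id, r$parent_id))
      }
      children_of[[r$parent_id]] <- c(children_of[[r$parent_id]], list(r))
    }
  }
  doc <- xml2::xml_new_root("rsml", version = "1.0")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "cm")
  xml2::xml_add_child(meta, "software", "rhizoconduct")
  scene <- xml2::xml_add_child(doc, "scene")
  if (length(tops) > 0) {
    plant <- xml2::xml_add_child(scene, "plant", ID = "1")
    for (r in tops) .write_root_node(plant, r, children_of)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Convert a simulated network's roots to RSML records
#'
#' One record per root organ, with the organ polyline rebuilt from its
#' segments, per-node radii and creation times, and the parent link at
#' the organ level. Optionally projects to the rhizotron (x-z) plane by
#' zeroing the y coordinate. The primary root is always first.
#'
#' @param net a \code{plant_network}.
#' @param project_2d zero the y coordinate (flat-rhizotron convention).
#' @return list of \code{rsml_root} records.
#' @export
network_to_rsml <- function(net, project_2d = FALSE) {
  s <- net$segments
  s <- s[s$type != "stem", , drop = FALSE]
  org <- net$organs
  org <- org[org$type %in% .root_types, , drop = FALSE]
  ord <- order(match(org$type, .root_types), org$emergence, org$organ)
  org <- org[ord, , drop = FALSE]
  out <- list()
  root_organ_ids <- org$organ
  for (i in seq_len(nrow(org))) {
    oid <- org$organ[i]
    seg <- s[s$organ == oid, , drop = FALSE]
    if (nrow(seg) == 0) next
    seg <- seg[order(seg$id), , drop = FALSE]
    poly <- rbind(c(seg$x0[1], seg$y0[1], seg$z0[1]),
                  cbind(seg$x1, seg$y1, seg$z1))
    if (project_2d) poly[, 2] <- 0
    ct <- c(seg$creation_time[1], seg$creation_time)
    parent <- org$parent_organ[i]
    parent_id <- if (!is.na(parent) && parent %in% root_organ_ids) {
      as.character(parent)
    } else NULL
    out[[length(out) + 1]] <- rsml_root(
      id = as.character(oid), polyline = poly, radius = seg$a[1],
      type = org$type[i], parent_id = parent_id, ctime = ct)
  }
  out
}
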