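#' NML and NMX skeleton annotation IO
#'
#' NML is the XML-based skeleton annotation dialect (format lineage:
#' KNOSSOS): a `things` document whose `thing` elements carry `nodes` and
#' `edges`, with node-level `comments` and a `parameters/scale` element
#' giving the voxel pitch in nm. An NMX file is a zip-archive container
#' holding one or more NML documents (e.g. the skeleton and soma outline
#' of one neuron, named `Neuron_id<ID>.nmx`).
#'
#' Coordinates in NML files are 1-based voxel indices; in memory the
#' package uses 0-based voxel indices. The conversion is lossless for
#' integer positions. Unknown node attributes are preserved verbatim for
#' round-tripping.
#'
#' @name nml
NULL

NML_NODE_ATTRS <- c("id", "x", "y", "z", "radius")

#' Construct an NML annotation
#'
#' @param skeletons list of [skeleton()] objects (voxel units).
#' @param comments data.frame with columns `node` (node id) and
#'   `content`, or NULL.
#' @param scale voxel pitch in nm, length 3.
#' @return object of class `"nml_annotation"`.
#' @export
nml_annotation <- function(skeletons = list(), comments = NULL,
                           scale = c(9.25, 9.25, 25)) {
  if (is.null(comments))
    comments <- data.frame(node = integer(0), content = character(0))
  structure(list(skeletons = skeletons, comments = comments,
                 scale = as.numeric(scale)),
            class = "nml_annotation")
}

#' @exportS3Method base::print
print.nml_annotation <- function(x, ...) {
  cat(sprintf("NML annotation: %d thing(s), %d comment(s), scale %g x %g x %g nm\n",
              length(x$skeletons), nrow(x$comments), x$scale[1],
              x$scale[2], x$scale[3]))
  invisible(x)
}

#' Parse an NML document
#'
#' @param x XML text, a file path, or an `xml2` document.
#' @return an [nml_annotation()].
#' @export
parse_nml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  scale <- c(9.25, 9.25, 25)
  sc <- xml2::xml_find_first(doc, ".//parameters/scale")
  if (!inherits(sc, "xml_missing")) {
    scale <- as.numeric(c(xml2::xml_attr(sc, "x"), xml2::xml_attr(sc, "y"),
                          xml2::xml_attr(sc, "z")))
  }
  skeletons <- list()
  for (thing in xml2::xml_find_all(doc, ".//thing")) {
    tid <- as.integer(xml2::xml_attr(thing, "id"))
    tname <- xml2::xml_attr(thing, "name")
    if (is.na(tname)) tname <- ""
    node_els <- xml2::xml_find_all(thing, ".//nodes/node")
    if (!length(node_els)) next
    attr_list <- lapply(node_els, xml2::xml_attrs)
    all_attrs <- unique(unlist(lapply(attr_list, names)))
    cols <- lapply(all_attrs, function(a)
      vapply(attr_list, function(at)
        if (a %in% names(at)) at[[a]] else NA_character_, ""))
    names(cols) <- all_attrs
    nodes <- data.frame(
      id = as.integer(cols$id),
      x = as.numeric(cols$x) - 1,       # NML is 1-based
      y = as.numeric(cols$y) - 1,
      z = as.numeric(cols$z) - 1,
      radius = if (!is.null(cols$radius)) as.numeric(cols$radius) else 1)
    for (a in setdiff(all_attrs, NML_NODE_ATTRS))
      nodes[[a]] <- cols[[a]]
    edge_els <- xml2::xml_find_all(thing, ".//edges/edge")
    edges <- if (length(edge_els)) {
      cbind(as.integer(xml2::xml_attr(edge_els, "source")),
            as.integer(xml2::xml_attr(edge_els, "target")))
    } else NULL
    if (!is.null(edges)) {
      missing <- setdiff(as.vector(edges), nodes$id)
      if (length(missing))
        stop("edge references missing node id(s): ",
             paste(missing, collapse = ", "))
    }
    skeletons[[length(skeletons) + 1L]] <-
      skeleton(nodes, edges, id = tid, name = tname, units = "voxel",
               scale = scale)
  }
  com_els <- xml2::xml_find_all(doc, ".//comments/comment")
  comments <- data.frame(
    node = as.integer(xml2::xml_attr(com_els, "node")),
    content = xml2::xml_attr(com_els, "content"))
  nml_annotation(skeletons, comments, scale)
}

num_attr <- function(v) {
  # shortest lossless decimal representation
  vapply(v, function(x) format(x, digits = 15, scientific = FALSE,
                               trim = TRUE), "")
}

#' Serialize an annotation to NML text
#'
#' Deterministic output: things, nodes, edges and comments are emitted in
#' sorted order, coordinates converted to the 1-based NML convention.
#'
#' @param ann an [nml_annotation()].
#' @param file optional path; when given, the text is also written there.
#' @return XML text (character scalar), invisibly when `file` is given.
#' @export
write_nml <- function(ann, file = NULL) {
  doc <- xml2::xml_new_root("things")
  par <- xml2::xml_add_child(doc, "parameters")
  xml2::xml_add_child(par, "scale", x = num_attr(ann$scale[1]),
                      y = num_attr(ann$scale[2]),
                      z = num_attr(ann$scale[3]))
  skels <- ann$skeletons
  if (length(skels))
    skels <- skels[order(vapply(skels, function(s) s$id, 0L))]
  for (sk in skels) {
    thing <- xml2::xml_add_child(doc, "thing", id = as.character(sk$id))
    if (nzchar(sk$name)) xml2::xml_set_attr(thing, "name", sk$name)
    nodes_el <- xml2::xml_add_child(thing, "nodes")
    nd <- sk$nodes[order(sk$nodes$id), , drop = FALSE]
    extra <- setdiff(names(nd), c(NML_NODE_ATTRS, "comment", "branch_id"))
    for (i in seq_len(nrow(nd))) {
      at <- list(id = as.character(nd$id[i]),
                 x = num_attr(nd$x[i] + 1),
                 y = num_attr(nd$y[i] + 1),
                 z = num_attr(nd$z[i] + 1),
                 radius = num_attr(nd$radius[i]))
      for (a in extra) if (!is.na(nd[[a]][i])) at[[a]] <- nd[[a]][i]
      do.call(xml2::xml_add_child, c(list(nodes_el, "node"), at))
    }
    edges_el <- xml2::xml_add_child(thing, "edges")
    if (nrow(sk$edges)) {
      e <- t(apply(sk$edges, 1, sort))
      e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
      for (i in seq_len(nrow(e)))
        xml2::xml_add_child(edges_el, "edge",
                            source = as.character(e[i, 1]),
                            target = as.character(e[i, 2]))
    }
  }
  if (nrow(ann$comments)) {
    com_el <- xml2::xml_add_child(doc, "comments")
    cm <- ann$comments[order(ann$comments$node), , drop = FALSE]
    for (i in seq_len(nrow(cm)))
      xml2::xml_add_child(com_el, "comment",
                          node = as.character(cm$node[i]),
                          content = cm$content[i])
  }
  txt <- as.character(doc)
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Read an NMX container
#'
#' @param path path to an NMX (zip) file.
#' @return object of class `"nmx_container"`: `entries` (named list of
#'   [nml_annotation()]), `source_name`, and `neuron_id` (parsed from a
#'   `Neuron_id<ID>.nmx` file name, else `NA`).
#' @export
read_nmx <- function(path) {
  magic <- readBin(path, "raw", 4)
  if (!identical(magic[1:2], charToRaw("PK")))
    stop("not a zip archive: ", path)
  exdir <- tempfile("nmx_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  entries <- list()
  for (f in files) {
    nm <- basename(f)
    ann <- try(parse_nml(f), silent = TRUE)
    if (inherits(ann, "try-error"))
      stop("entry '", nm, "' failed to parse: ",
           attr(ann, "condition")$message)
    entries[[nm]] <- ann
  }
  if (!length(entries)) stop("NMX container has no entries")
  id <- NA_integer_
  m <- regmatches(basename(path),
                  regexec("^Neuron_id([0-9]+)\\.nmx$", basename(path)))[[1]]
  if (length(m) == 2) id <- as.integer(m[2])
  structure(list(entries = entries, source_name = basename(path),
                 neuron_id = id),
            class = "nmx_container")
}

#' Write an NMX container
#'
#' @param annotations a single [nml_annotation()] or a named list of
#'   them; unnamed entries are named `annotation<N>.nml`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nmx <- function(annotations, path) {
  if (inherits(annotations, "nml_annotation"))
    annotations <- list(annotation1.nml = annotations)
  nms <- names(annotations)
  if (is.null(nms)) nms <- rep("", length(annotations))
  blank <- !nzchar(nms)
  nms[blank] <- sprintf("annotation%d.nml", which(blank))
  if (anyDuplicated(nms)) stop("entry names must be unique")
  entries <- stats::setNames(lapply(annotations, write_nml), nms)
  write_zip_stored(path, entries)
  invisible(path)
}

#' @exportS3Method base::print
print.nmx_container <- function(x, ...) {
  cat(sprintf("NMX container '%s': %d entries%s\n", x$source_name,
              length(x$entries),
              if (!is.na(x$neuron_id))
                paste0(" (neuron id ", x$neuron_id, ")") else ""))
  invisible(x)
}

#' Build a synapse-triplet annotation
#'
#' A synapse is annotated by three successive connected nodes: on the
#' presynaptic neuron, at the synaptic cleft, and on the postsynaptic
#' neuron. The triplet is serialized as a 3-node, 2-edge thing with node
#' comments `pre`, `cleft:<class>:<confidence>`, `post`, preserving the
#' pre -> cleft -> post order and the user-defined class and ordinal
#' confidence.
#'
#' @param pre,cleft,post numeric length-3 voxel positions.
#' @param class_label synapse class (user-defined vocabulary).
#' @param confidence ordinal confidence level.
#' @param thing_id id of the created thing.
#' @param node_ids ids of the three nodes.
#' @return an [nml_annotation()] with one thing.
#' @export
synapse_annotation <- function(pre, cleft, post, class_label = "synapse",
                               confidence = 1L, thing_id = 1L,
                               node_ids = 1:3) {
  pos <- rbind(pre, cleft, post)
  nodes <- data.frame(id = node_ids, x = pos[, 1], y = pos[, 2],
                      z = pos[, 3], radius = 1)
  sk <- skeleton(nodes, cbind(node_ids[1:2], node_ids[2:3]),
                 id = thing_id, name = "synapse", units = "voxel")
  comments <- data.frame(
    node = node_ids,
    content = c("pre",
                paste("cleft", class_label, confidence, sep = ":"),
                "post"))
  nml_annotation(list(sk), comments)
}

#' Extract synapse triplets from an annotation
#'
#' @param ann an [nml_annotation()].
#' @return data.frame with one row per synapse: node ids, positions,
#'   `class_label` and `confidence`.
#' @export
extract_synapses <- function(ann) {
  cm <- ann$comments
  cleft <- cm[grepl("^cleft:", cm$content), , drop = FALSE]
  out <- list()
  for (sk in ann$skeletons) {
    for (i in seq_len(nrow(cleft))) {
      cid <- cleft$node[i]
      if (!(cid %in% sk$nodes$id)) next
      nb <- sk$edges[sk$edges[, 1] == cid | sk$edges[, 2] == cid, ,
                     drop = FALSE]
      nbr <- setdiff(as.vector(nb), cid)
      pre <- intersect(nbr, cm$node[cm$content == "pre"])
      post <- intersect(nbr, cm$node[cm$content == "post"])
      if (length(pre) != 1 || length(post) != 1) next
      parts <- strsplit(cleft$content[i], ":", fixed = TRUE)[[1]]
      out[[length(out) + 1L]] <- data.frame(
        pre_node = pre, cleft_node = cid, post_node = post,
        class_label = parts[2], confidence = as.integer(parts[3]))
    }
  }
  if (!length(out))
    return(data.frame(pre_node = integer(0), cleft_node = integer(0),
                      post_node = integer(0), class_label = character(0),
                      confidence = integer(0)))
  do.call(rbind, out)
}

#' Build a soma-outline annotation
#'
#' Soma outlines are convex point sets (at least 4 non-coplanar points)
#' from which a hull can be rendered; serialized as an edge-less thing
#' named `soma_<owner>`.
#'
#' @param points n x 3 matrix of voxel positions, n >= 4.
#' @param owner owning neuron id.
#' @param thing_id id of the created thing.
#' @return an [nml_annotation()] with one thing.
#' @export
soma_outline <- function(points, owner, thing_id = 1L) {
  if (nrow(points) < 4) stop("a soma outline needs at least 4 points")
  nodes <- data.frame(id = seq_len(nrow(points)), x = points[, 1],
                      y = points[, 2], z = points[, 3], radius = 1)
  sk <- skeleton(nodes, NULL, id = thing_id,
                 name = paste0("soma_", owner), units = "voxel")
  nml_annotation(list(sk))
}

CELL_TYPES <- c("mitral", "IN1", "IN2", "IN3", "UPN", "LOC", "other")

#' Read an innervation table CSV
#'
#' The table lists the neurite path length (micrometres) of each neuron
#' in each glomerulus: columns `neuron_id`, `cell_type`, then one column
#' per glomerulus. Recognized cell types are mitral cells, interneuron
#' classes 1-3, unusual projection neurons (UPN), large olfactory bulb
#' cells (LOC) and `other`; unknown labels are mapped to `other` with a
#' warning.
#'
#' @param path CSV path (lines starting with `#` are ignored).
#' @return data.frame of class `"innervation_table"`.
#' @export
read_innervation_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(c("neuron_id", "cell_type") %in% names(df)))
    stop("innervation table must have neuron_id and cell_type columns")
  regions <- setdiff(names(df), c("neuron_id", "cell_type"))
  for (r in regions) {
    v <- suppressWarnings(as.numeric(df[[r]]))
    if (nrow(df) && anyNA(v))
      stop("non-numeric length in column '", r, "'")
    df[[r]] <- v
  }
  unknown <- !(df$cell_type %in% CELL_TYPES)
  if (any(unknown)) {
    warning("unknown cell type(s) mapped to 'other': ",
            paste(unique(df$cell_type[unknown]), collapse = ", "))
    df$cell_type[unknown] <- "other"
  }
  class(df) <- c("innervation_table", "data.frame")
  df
}

#' Write an innervation table CSV
#'
#' @param table an innervation table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_innervation_csv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# neurite length per glomerulus in micrometers", con)
  utils::write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
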