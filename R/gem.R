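#' ICD-9/ICD-10 general equivalence mapping as a bipartite graph
#'
#' Builds a `gem_graph` from an edge list. Codes are normalised (dots and
#' whitespace stripped, upper-cased) so that dotted event codes match the
#' dotless GEM convention. Isolated vertices may be supplied so that codes
#' absent from every edge still become singleton groups.
#'
#' @param edges data frame with columns `icd9` and `icd10`, one edge per row.
#' @param isolated_icd9,isolated_icd10 optional character vectors of codes
#'   with no crosswalk edge.
#' @return an object of class `gem_graph`.
#' @export
gem_graph <- function(edges, isolated_icd9 = character(),
                      isolated_icd10 = character()) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && !all(c("icd9", "icd10") %in% names(edges))) {
    stop("edges must have columns icd9 and icd10", call. = FALSE)
  }
  i9 <- normalize_code(if (nrow(edges)) edges$icd9 else character())
  i10 <- normalize_code(if (nrow(edges)) edges$icd10 else character())
  if (any(i9 == "") || any(i10 == "")) {
    stop("malformed GEM edge: empty code", call. = FALSE)
  }
  e <- unique(data.frame(icd9 = i9, icd10 = i10, stringsAsFactors = FALSE))
  g <- list(edges = e,
            icd9_vertices = sort(unique(c(e$icd9, normalize_code(isolated_icd9)))),
            icd10_vertices = sort(unique(c(e$icd10, normalize_code(isolated_icd10)))))
  g$icd9_vertices <- g$icd9_vertices[g$icd9_vertices != ""]
  g$icd10_vertices <- g$icd10_vertices[g$icd10_vertices != ""]
  class(g) <- "gem_graph"
  g
}

#' Read a tab-delimited GEM crosswalk file
#'
#' @param path headerless tab-delimited file, `icd9<TAB>icd10` per line.
#' @return a [gem_graph()].
#' @export
read_gem_file <- function(path) {
  if (file.size(path) == 0) {
    return(gem_graph(data.frame(icd9 = character(), icd10 = character())))
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           col.names = c("icd9", "icd10"))
  gem_graph(raw)
}

normalize_code <- function(x) toupper(gsub("[.[:space:]]", "", as.character(x)))

#' Decompose a GEM graph into minimal disjoint bipartite groups
#'
#' Treats the crosswalk as an undirected bipartite graph with ICD-9 and
#' ICD-10 codes as the two vertex sets and computes its connected
#' components: the unique finest partition whose groups cannot be split
#' without breaking a crosswalk edge. Each component becomes a code group
#' spanning the coding transition; isolated vertices become singleton
#' groups. Group ids are deterministic: the namespace-prefixed
#' lexicographically smallest member code.
#'
#' @param graph a [gem_graph()].
#' @return an object of class `code_groups`: a data frame with columns
#'   `group_id`, `namespace` (`"ICD9"`/`"ICD10"`) and `code`, one row per
#'   member code.
#' @export
decompose_gem <- function(graph) {
  stopifnot(inherits(graph, "gem_graph"))
  # sprintf (unlike paste0) keeps zero-length inputs zero-length
  v9 <- sprintf("9:%s", graph$icd9_vertices)
  v10 <- sprintf("10:%s", graph$icd10_vertices)
  verts <- c(v9, v10)
  if (length(verts) == 0) {
    out <- data.frame(group_id = character(), namespace = character(),
                      code = character(), stringsAsFactors = FALSE)
    class(out) <- c("code_groups", "data.frame")
    return(out)
  }
  if (nrow(graph$edges) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("9:", graph$edges$icd9),
                 to = paste0("10:", graph$edges$icd10)),
      directed = FALSE, vertices = verts)
  } else {
    g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = verts)
  }
  comp <- igraph::components(g)$membership
  nm <- names(comp)
  ns <- ifelse(startsWith(nm, "9:"), "ICD9", "ICD10")
  code <- sub("^(9|10):", "", nm)
  ## deterministic id: smallest member code (ties broken toward ICD9)
  ord <- order(comp, code, ns)
  first <- !duplicated(comp[ord])
  gid_by_comp <- paste0(ns[ord][first], ":", code[ord][first])
  names(gid_by_comp) <- comp[ord][first]
  out <- data.frame(group_id = unname(gid_by_comp[as.character(comp)]),
                    namespace = ns, code = code, stringsAsFactors = FALSE)
  out <- out[order(out$group_id, out$namespace, out$code), ]
  rownames(out) <- NULL
  class(out) <- c("code_groups", "data.frame")
  out
}

#' Map diagnosis events to era-spanning group codes
#'
#' Looks each ICD event up on its own side of the crosswalk groups: ICD-9
#' events against the groups' ICD-9 members, ICD-10 events against the
#' ICD-10 members. Codes absent from every group map to a deterministic
#' singleton id `"<system>:<code>"` rather than being dropped.
#'
#' @param events data frame with columns `system` (`"ICD9"`/`"ICD10"`) and
#'   `code`; other systems are an error.
#' @param groups a [decompose_gem()] result.
#' @return character vector of group ids, one per event.
#' @export
map_events <- function(events, groups) {
  stopifnot(inherits(groups, "code_groups") || is.data.frame(groups))
  if (nrow(events) == 0) return(character())
  bad <- !(events$system %in% c("ICD9", "ICD10"))
  if (any(bad)) {
    stop("map_events only accepts ICD9/ICD10 events; got: ",
         paste(unique(events$system[bad]), collapse = ", "), call. = FALSE)
  }
  code <- normalize_code(events$code)
  lut9 <- groups$group_id[groups$namespace == "ICD9"]
  names(lut9) <- groups$code[groups$namespace == "ICD9"]
  lut10 <- groups$group_id[groups$namespace == "ICD10"]
  names(lut10) <- groups$code[groups$namespace == "ICD10"]
  out <- character(nrow(events))
  is9 <- events$system == "ICD9"
  out[is9] <- unname(lut9[code[is9]])
  out[!is9] <- unname(lut10[code[!is9]])
  miss <- is.na(out)
  out[miss] <- paste0(events$system[miss], ":", code[miss])
  out
}

#' @rdname map_events
#' @param system,code scalar system and code for a single event.
#' @export
map_event <- function(system, code, groups) {
  map_events(data.frame(system = system, code = code,
                        stringsAsFactors = FALSE), groups)
}

#' Write code groups as CSV
#' @param groups a [decompose_gem()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_code_groups <- function(groups, path) {
  utils::write.csv(as.data.frame(groups), path, row.names = FALSE)
  invisible(path)
}
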