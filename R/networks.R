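# Ego-centric kin network assembly.
#
# Four ego groups are analysed separately (each ethnicity x sex), but an
# ego's connections may be of any sex and any ethnicity. A network is the
# union of ego-alter star graphs over all qualifying egos: edges run only
# between an ego and its close biological kin (relatedness >= 0.5) or its
# affinal kin (partner, partner's parents and full siblings). Both
# endpoints must have a known value of the focal trait; egos with no
# qualifying alter are dropped.

#' Build an ego-group kin network
#'
#' @param census A `census` data frame.
#' @param matrix A [relatedness_matrix()] over the same individuals.
#' @param tie_type `"biological"` (close kin, relatedness >= `threshold`) or
#'   `"affinal"` (partner, partner's parents and full siblings).
#' @param ego_filter List with elements `ethnicity` and `sex` selecting the
#'   ego group; alters are unrestricted.
#' @param trait Focal trait (`"mandarin"`, `"sichuan"`, `"naru"`,
#'   `"jeans"`).
#' @param jeans_scheme Jeans binarization, see [binarize_jeans()].
#' @param threshold Relatedness threshold for biological ties (default 0.5).
#' @param config A [survey_config()].
#' @return An [igraph::graph] with vertex attributes `name` (person id),
#'   `label_value` (0/1 trait value) and `is_ego`; edge attributes
#'   `tie_type` and `weight` (coded relatedness). Graph attributes record
#'   the ego group, trait and tie type.
#' @export
build_network <- function(census, matrix, tie_type = c("biological", "affinal"),
                          ego_filter = list(ethnicity = NULL, sex = NULL),
                          trait = "mandarin", jeans_scheme = "high",
                          threshold = 0.5, config = survey_config()) {
  tie_type <- match.arg(tie_type)
  vals <- trait_values(census, trait, jeans_scheme)
  age <- age_at_survey(census, config)
  known <- census$surveyed %in% 1L & !is.na(vals) & !is.na(age) &
    age >= config$adult_age
  ids <- census$person_id

  is_ego <- known
  if (!is.null(ego_filter$ethnicity)) {
    is_ego <- is_ego & census$ethnicity %in% ego_filter$ethnicity
  }
  if (!is.null(ego_filter$sex)) {
    is_ego <- is_ego & census$sex %in% ego_filter$sex
  }
  egos <- ids[which(is_ego)]
  if (length(egos) == 0) {
    stop("empty ego set for trait '", trait, "' with the given filter")
  }

  known_ids <- ids[known]
  from <- character(0); to <- character(0); w <- numeric(0)
  for (e in egos) {
    alters <- if (tie_type == "biological") {
      close_biological_kin(matrix, e, threshold)
    } else {
      affinal_kin(census, matrix, e)
    }
    alters <- alters[names(alters) %in% known_ids]
    if (length(alters) == 0) next
    from <- c(from, rep(e, length(alters)))
    to <- c(to, names(alters))
    w <- c(w, unname(alters))
  }
  if (length(from) == 0) {
    stop("no ", tie_type, " ties among surveyed individuals for trait '",
         trait, "'")
  }
  # deduplicate undirected edges (an edge seen from both ego directions)
  key_ab <- pmin(from, to)
  key_ba <- pmax(from, to)
  keep <- !duplicated(paste(key_ab, key_ba, sep = "\r"))
  from <- from[keep]; to <- to[keep]; w <- w[keep]

  nodes <- unique(c(from, to))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w, tie_type = tie_type,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(
      name = nodes,
      label_value = vals[match(nodes, ids)],
      is_ego = nodes %in% egos,
      stringsAsFactors = FALSE
    )
  )
  g <- igraph::set_graph_attr(g, "trait", trait)
  g <- igraph::set_graph_attr(g, "tie_type", tie_type)
  g <- igraph::set_graph_attr(
    g, "ego_group",
    paste(c(ego_filter$ethnicity, ego_filter$sex), collapse = " "))
  g
}

#' Number of an ego's kin who adopt the focal trait
#'
#' Counts the ego's network neighbours whose trait label is 1. This is the
#' kin-adoption-count predictor used by downstream regression analyses.
#'
#' @param network A [build_network()] graph.
#' @param ego A person id present in the network.
#' @return Integer count.
#' @export
kin_adoption_count <- function(network, ego) {
  if (!ego %in% igraph::V(network)$name) {
    stop("ego not in network: ", ego)
  }
  nb <- igraph::neighbors(network, ego)
  sum(nb$label_value == 1L, na.rm = TRUE)
}

#' Export a network's edges and node labels
#'
#' @param network A [build_network()] graph.
#' @param edge_path,node_path Output CSV paths (either may be `NULL`).
#' @return Invisibly, a list with the two data frames.
#' @export
write_network <- function(network, edge_path = NULL, node_path = NULL) {
  ed <- igraph::as_data_frame(network, what = "edges")
  nd <- igraph::as_data_frame(network, what = "vertices")
  names(nd)[names(nd) == "name"] <- "person_id"
  if (!is.null(edge_path)) {
    utils::write.csv(ed, edge_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(node_path)) {
    utils::write.csv(nd, node_path, row.names = FALSE, quote = FALSE)
  }
  invisible(list(edges = ed, nodes = nd))
}
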