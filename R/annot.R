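gff_attr <- function(attributes, key) {
  m <- stringr::str_match(attributes, paste0("(?:^|;)\\s*", key, "=([^;]*)"))
  m[, 2]
}

#' Read gene models from a GFF3 annotation
#'
#' Parses `gene`-type records (1-based inclusive coordinates) and, when
#' present, their Gene Ontology annotations from the `Ontology_term`
#' attribute with namespaces from a parallel `go_namespace` attribute
#' (comma-separated `MF`/`BP`/`CC` labels, the convention used by the
#' bundled synthetic annotations).
#'
#' @param path GFF3 file path.
#' @param feature Feature type to keep (default `"gene"`).
#' @return Tibble `gene_id`, `chromosome`, `start_bp`, `end_bp`, `strand`,
#'   `go_terms` (list-column of tibbles `term_id`, `namespace`).
#' @export
read_gene_models <- function(path, feature = "gene") {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- ape::read.gff(path)
  g <- g[g$type == feature, , drop = FALSE]
  terms <- gff_attr(as.character(g$attributes), "Ontology_term")
  nss <- gff_attr(as.character(g$attributes), "go_namespace")
  go <- purrr::map2(terms, nss, function(tm, ns) {
    if (is.na(tm) || !nzchar(tm)) {
      return(tibble::tibble(term_id = character(), namespace = character()))
    }
    tm <- strsplit(tm, ",")[[1]]
    ns <- if (is.na(ns)) rep(NA_character_, length(tm)) else strsplit(ns, ",")[[1]]
    bad <- !grepl("^GO:\\d+$", tm)
    if (any(bad)) {
      warning("malformed GO term id(s): ", paste(tm[bad], collapse = ", "))
    }
    tibble::tibble(term_id = tm, namespace = rep_len(ns, length(tm)))
  })
  tibble::tibble(
    gene_id = gff_attr(as.character(g$attributes), "ID"),
    chromosome = as.character(g$seqid),
    start_bp = as.integer(g$start), end_bp = as.integer(g$end),
    strand = as.character(g$strand),
    go_terms = go)
}

#' Gene models overlapping a hotspot physical interval
#'
#' Returns the genes whose 1-based inclusive `[start_bp, end_bp]` span
#' intersects the hotspot's flanking-marker interval
#' `[min(left_bp, right_bp), max(left_bp, right_bp)]` (closed-interval
#' overlap, so a gene touching the interval at a single bp is included),
#' ordered by start position. The result does not depend on the record
#' order of the annotation.
#'
#' @param hotspot One row of a `hotspot_table`, or any list/row with
#'   `chromosome`, `left_bp`, `right_bp`.
#' @param annotation Gene-model tibble from [read_gene_models()] or a GFF3
#'   path.
#' @return The overlapping gene-model rows.
#' @export
genes_in_hotspot <- function(hotspot, annotation) {
  if (is.character(annotation)) annotation <- read_gene_models(annotation)
  genes <- tibble::as_tibble(annotation)
  h <- as.list(hotspot)
  lo <- min(h$left_bp, h$right_bp)
  hi <- max(h$left_bp, h$right_bp)
  if (!h$chromosome %in% genes$chromosome) {
    stop("chromosome '", h$chromosome, "' absent from annotation")
  }
  hit <- genes$chromosome == h$chromosome &
    genes$start_bp <= hi & genes$end_bp >= lo
  dplyr::arrange(genes[hit, ], .data$start_bp, .data$gene_id)
}

#' Summarise Gene Ontology annotation of a gene set
#'
#' Counts genes and distinct terms within each of the three GO namespaces
#' (molecular function, biological process, cellular component); genes
#' without any term are counted separately. A gene carrying several terms
#' of one namespace counts once toward that namespace's gene count.
#'
#' @param genes Gene-model tibble with a `go_terms` list-column.
#' @return List with `namespaces` (tibble `namespace`, `n_genes`,
#'   `n_terms`), `terms` (tibble `namespace`, `term_id`, `n_genes`) and
#'   `n_unannotated`.
#' @export
go_summary <- function(genes) {
  genes <- tibble::as_tibble(genes)
  n_terms_per_gene <- purrr::map_int(genes$go_terms, nrow)
  flat <- dplyr::bind_rows(
    purrr::map2(genes$gene_id, genes$go_terms,
                ~ dplyr::mutate(.y, gene_id = .x)))
  ns_levels <- c("MF", "BP", "CC")
  if (nrow(flat)) {
    per_ns <- dplyr::summarise(
      dplyr::group_by(flat, .data$namespace),
      n_genes = dplyr::n_distinct(.data$gene_id),
      n_terms = dplyr::n(), .groups = "drop")
  } else {
    per_ns <- tibble::tibble(namespace = character(), n_genes = integer(),
                             n_terms = integer())
  }
  namespaces <- dplyr::left_join(
    tibble::tibble(namespace = ns_levels), per_ns, by = "namespace")
  namespaces[is.na(namespaces)] <- 0L
  terms <- if (nrow(flat)) {
    dplyr::arrange(
      dplyr::summarise(
        dplyr::group_by(flat, .data$namespace, .data$term_id),
        n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop"),
      .data$namespace, dplyr::desc(.data$n_genes))
  } else {
    tibble::tibble(namespace = character(), term_id = character(),
                   n_genes = integer())
  }
  list(namespaces = namespaces, terms = terms,
       n_unannotated = sum(n_terms_per_gene == 0))
}
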