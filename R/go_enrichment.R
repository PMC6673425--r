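# Over-representation analysis of a candidate gene list against
# term -> gene annotations (hypergeometric and EASE variants).

#' Construct a gene-set collection
#'
#' @param terms data frame with columns `term_id`, `name`, `category`
#'   (e.g. BP/MF/CC) and a list-column `members` of character vectors, or a
#'   named list of character vectors (names become term ids, category
#'   `"NA"`).
#' @param universe background gene set; defaults to the union of all term
#'   members. Term members outside the universe are an error.
#' @return a `gene_set_collection` (list with `terms`, `universe`).
#' @export
gene_set_collection <- function(terms, universe = NULL) {
  if (!is.data.frame(terms) && is.list(terms) && !is.null(names(terms))) {
    # named list of member vectors -> minimal terms frame
    ids <- names(terms)
    members <- unname(terms)
    terms <- data.frame(term_id = ids, name = ids, category = "NA",
                        stringsAsFactors = FALSE)
    terms$members <- members
  }
  needed <- c("term_id", "name", "category", "members")
  assert_that(all(needed %in% names(terms)),
              "terms needs columns term_id, name, category, members")
  assert_that(!anyDuplicated(terms$term_id), "term_id values must be unique")
  members <- lapply(terms$members, function(g) unique(as.character(g)))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(members)))
  } else {
    universe <- unique(as.character(universe))
    outside <- setdiff(unlist(members), universe)
    assert_that(length(outside) == 0,
                sprintf("term members outside the universe: %s",
                        paste(utils::head(outside, 5), collapse = ", ")))
  }
  assert_that(length(universe) > 0, "universe must be non-empty")
  terms$members <- members
  structure(list(terms = terms, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d terms over %d universe genes\n",
              nrow(x$terms), length(x$universe)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' GMT: one term per line, `term_id <tab> description <tab> gene1 <tab>
#' gene2 ...`. Term categories can be encoded as a `CATEGORY:` prefix on
#' the description (e.g. `BP:regulation of cell shape`); otherwise the
#' category is `"NA"`.
#'
#' @param path GMT file path.
#' @param universe optional background gene list; default union of members.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  assert_that(file.exists(path), sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  assert_that(length(lines) > 0, "GMT file is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  assert_that(all(lengths(parts) >= 3),
              "each GMT line needs term, description, and >= 1 gene")
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  cat_match <- regmatches(desc, regexec("^([A-Za-z]+):(.*)$", desc))
  category <- vapply(cat_match, function(m) if (length(m)) m[2] else "NA",
                     character(1))
  name <- vapply(seq_along(desc), function(i) {
    m <- cat_match[[i]]
    if (length(m)) m[3] else desc[i]
  }, character(1))
  terms <- data.frame(term_id = ids, name = name, category = category,
                      stringsAsFactors = FALSE)
  terms$members <- lapply(parts, function(p) unique(p[-(1:2)]))
  gene_set_collection(terms, universe)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  tr <- collection$terms
  desc <- ifelse(tr$category == "NA", tr$name,
                 paste0(tr$category, ":", tr$name))
  lines <- vapply(seq_len(nrow(tr)), function(i) {
    paste(c(tr$term_id[i], desc[i], tr$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail enrichment p-value
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: drawing `n` query genes
#' from a universe of `N` genes of which `K` belong to the term, the
#' probability of observing `k` or more term genes by chance.
#'
#' @param k observed overlap count.
#' @param K term size.
#' @param n query size.
#' @param N universe size; requires `0 <= k <= min(K, n) <= N`.
#' @return p in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N) {
  assert_that(all(c(k, K, n, N) >= 0) && k <= min(K, n) && K <= N && n <= N,
              "need 0 <= k <= min(K, n) <= N")
  if (k == 0) return(1)
  # exact tail sum; phyper's upper tail excludes k itself, hence k - 1
  min(1, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' EASE-adjusted enrichment p-value
#'
#' The conservative variant of the hypergeometric tail: one overlapping
#' gene is removed (`k -> max(k - 1, 0)`) before computing the tail, which
#' penalises terms supported by a single gene (their p becomes 1).
#'
#' @inheritParams hypergeom_p
#' @return p in (0, 1], always >= the plain hypergeometric p.
#' @export
ease_p <- function(k, K, n, N) {
  hypergeom_p(max(k - 1, 0), K, n, N)
}

#' Over-representation analysis of a gene list
#'
#' Tests every term in the collection for over-representation of the query
#' genes, with either the plain hypergeometric upper tail or the EASE
#' variant. Query genes outside the universe are dropped with a warning.
#' Results are sorted by ascending p, ties broken by term id, so the
#' ranking is invariant to input ordering.
#'
#' @param query character vector of candidate gene symbols.
#' @param collection a [gene_set_collection()].
#' @param method `"hypergeometric"` (default) or `"ease"`.
#' @param p_thresh significance threshold for the `significant` flag,
#'   default 0.05 (raw p, strict).
#' @param adjust also report Benjamini-Hochberg q-values (`q` column);
#'   off by default.
#' @return data frame with columns `term_id`, `name`, `category`, `k`,
#'   `K`, `n`, `N`, `p`, `significant` (and `q` when `adjust = TRUE`).
#' @export
enrich <- function(query, collection, method = c("hypergeometric", "ease"),
                   p_thresh = 0.05, adjust = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- collection$universe
  assert_that(length(universe) > 0, "universe must be non-empty")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
    query <- setdiff(query, outside)
  }
  N <- length(universe)
  n <- length(query)
  tr <- collection$terms
  pfun <- if (method == "ease") ease_p else hypergeom_p
  res <- lapply(seq_len(nrow(tr)), function(i) {
    members <- tr$members[[i]]
    K <- length(members)
    k <- length(intersect(query, members))
    data.frame(term_id = tr$term_id[i], name = tr$name[i],
               category = tr$category[i],
               k = k, K = K, n = n, N = N,
               p = pfun(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < p_thresh
  out
}
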