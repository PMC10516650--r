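#' Shipped 16S rRNA domain boundaries
#'
#' Head/body domain boundaries for small-subunit motion analysis, shipped
#' as versioned package data rather than code constants because published
#' motion measurements never enumerate the exact residue sets they
#' aligned on. The `Ecoli-16S` scheme defines the head as the 3' major
#' domain (residues 930-1390) and the body as the remainder; the
#' `Sac-16S` scheme ports those boundaries to *Sulfolobus acidocaldarius*
#' numbering with piecewise offsets anchored on stated residue
#' correspondences (Sac G1307 to E. coli G1338; Sac G496 to E. coli
#' G530).
#'
#' @param scheme numbering scheme tag, e.g. `"Ecoli-16S"` or `"Sac-16S"`;
#'   `NULL` lists all schemes.
#' @param domain optional domain name (`"head"`, `"body"`); `NULL` gives
#'   all domains of the scheme.
#' @return a tibble with columns `scheme`, `domain`, `start`, `end`, or,
#'   when both `scheme` and `domain` are given, a list of inclusive
#'   `c(start, end)` ranges ready for [select_atoms()]'s `residues`
#'   argument.
#' @export
domain_definitions <- function(scheme = NULL, domain = NULL) {
  path <- system.file("extdata", "ssu_16S_domains.tsv",
                      package = "cryoquant", mustWork = TRUE)
  tab <- tibble::as_tibble(utils::read.delim(path, comment.char = "#"))
  if (is.null(scheme)) return(tab)
  tab <- tab[tab$scheme == scheme, , drop = FALSE]
  if (nrow(tab) == 0) {
    stop("unknown numbering scheme: ", scheme, " (available: ",
         paste(unique(domain_definitions()$scheme), collapse = ", "), ")",
         call. = FALSE)
  }
  if (is.null(domain)) return(tab)
  tab <- tab[tab$domain == domain, , drop = FALSE]
  if (nrow(tab) == 0) stop("unknown domain: ", domain, call. = FALSE)
  unname(lapply(seq_len(nrow(tab)), function(i) c(tab$start[i], tab$end[i])))
}
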