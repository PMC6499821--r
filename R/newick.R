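#' Write a tree to a Newick string or file
#'
#' Serializes an [ape::phylo] tree with branch lengths.  Labels containing
#' characters with structural meaning in Newick (whitespace, parentheses,
#' commas, colons, semicolons, quotes) are single-quoted, with embedded
#' quotes doubled, so that [read_newick()] round-trips topology, labels and
#' branch lengths exactly.  Children are written in the order stored in the
#' tree.
#'
#' @param tree an object of class `phylo`.
#' @param file optional path; if given the string is written there.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  quote_label <- function(x) {
    if (is.na(x) || !nzchar(x)) return("")
    if (grepl("[][\\s(),:;'\"]", x, perl = TRUE))
      paste0("'", gsub("'", "''", x), "'")
    else x
  }
  lab <- function(i) {
    if (i <= n_tip) quote_label(tree$tip.label[i])
    else if (!is.null(tree$node.label)) quote_label(tree$node.label[i - n_tip])
    else ""
  }
  fmt_len <- function(e) {
    if (is.null(tree$edge.length)) ""
    else paste0(":", format(tree$edge.length[e], digits = digits, scientific = FALSE))
  }
  recurse <- function(i, edge_in) {
    ks <- kids[[as.character(i)]]
    body <- if (is.null(ks)) lab(i) else {
      paste0("(",
             paste(vapply(ks, function(e) recurse(tree$edge[e, 2], e), ""),
                   collapse = ","),
             ")", lab(i))
    }
    if (is.na(edge_in)) body else paste0(body, fmt_len(edge_in))
  }
  s <- paste0(recurse(root, NA_integer_), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Read a tree from a Newick string or file
#'
#' A small recursive-descent parser supporting quoted labels (single quotes,
#' `''` escapes) and branch lengths.  Malformed input raises an error naming
#' the character position.
#'
#' @param text a Newick string (used when `file` is `NULL`).
#' @param file optional path to read from.
#' @return an object of class `phylo`.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  if (is.null(text) || !nzchar(trimws(text))) stop("empty Newick input")
  s <- trimws(text)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- 1L
  n <- length(chars)

  err <- function(msg) stop("Newick parse error at position ", pos, ": ", msg)
  peek <- function() if (pos <= n) chars[pos] else ""
  advance <- function() { pos <<- pos + 1L }
  skip_ws <- function() while (pos <= n && grepl("\\s", chars[pos])) pos <<- pos + 1L

  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      advance()
      out <- character(0)
      repeat {
        if (pos > n) err("unterminated quoted label")
        ch <- chars[pos]
        if (ch == "'") {
          if (pos + 1L <= n && chars[pos + 1L] == "'") { out <- c(out, "'"); pos <<- pos + 2L }
          else { advance(); break }
        } else { out <- c(out, ch); advance() }
      }
      paste(out, collapse = "")
    } else {
      out <- character(0)
      while (pos <= n && !chars[pos] %in% c("(", ")", ",", ":", ";") &&
             !grepl("\\s", chars[pos])) {
        out <- c(out, chars[pos]); advance()
      }
      paste(out, collapse = "")
    }
  }
  read_length <- function() {
    skip_ws()
    if (peek() != ":") return(NA_real_)
    advance(); skip_ws()
    start <- pos
    while (pos <= n && grepl("[-+0-9eE.]", chars[pos])) advance()
    if (pos == start) err("expected branch length after ':'")
    v <- suppressWarnings(as.numeric(paste(chars[start:(pos - 1L)], collapse = "")))
    if (is.na(v)) err("invalid branch length")
    v
  }

  # Build flat node records: list(label, length, children indices)
  nodes <- list()
  new_node <- function(label, len, kids) {
    nodes[[length(nodes) + 1L]] <<- list(label = label, len = len, kids = kids)
    length(nodes)
  }
  parse_clade <- function() {
    skip_ws()
    if (peek() == "(") {
      advance()
      kids <- c(parse_clade())
      skip_ws()
      while (peek() == ",") { advance(); kids <- c(kids, parse_clade()); skip_ws() }
      if (peek() != ")") err("expected ')' or ','")
      advance()
      lab <- read_label()
      len <- read_length()
      new_node(lab, len, kids)
    } else {
      lab <- read_label()
      if (!nzchar(lab) && !peek() %in% c(":", ",", ")"))
        err("expected a label or '('")
      len <- read_length()
      new_node(lab, len, integer(0))
    }
  }
  root_id <- parse_clade()
  skip_ws()
  if (peek() != ";") err("expected ';'")
  advance(); skip_ws()
  if (pos <= n) err("trailing characters after ';'")
  if (length(nodes[[root_id]]$kids) == 0L)  # single-tip tree: add a root above
    root_id <- new_node("", NA_real_, root_id)

  is_tip <- vapply(nodes, function(x) length(x$kids) == 0L, TRUE)
  n_tip <- sum(is_tip)
  if (n_tip < 1L) err("no tips")
  tip_idx <- integer(length(nodes)); internal_counter <- n_tip + 1L; tip_counter <- 0L
  # preorder numbering with root = n_tip + 1
  assign_num <- local({
    num <- integer(length(nodes))
    rec <- function(i) {
      if (is_tip[i]) { tip_counter <<- tip_counter + 1L; num[i] <<- tip_counter }
      else { num[i] <<- internal_counter; internal_counter <<- internal_counter + 1L
             for (k in nodes[[i]]$kids) rec(k) }
    }
    rec(root_id)
    num
  })
  edge <- NULL; edge_len <- numeric(0)
  collect <- function(i) {
    for (k in nodes[[i]]$kids) {
      edge <<- rbind(edge, c(assign_num[i], assign_num[k]))
      edge_len <<- c(edge_len, nodes[[k]]$len)
      collect(k)
    }
  }
  collect(root_id)
  tips_order <- order(assign_num[is_tip])
  tip_labels <- vapply(nodes[is_tip], function(x) x$label, "")[tips_order]
  node_labels <- vapply(nodes[!is_tip], function(x) x$label, "")
  node_labels <- node_labels[order(assign_num[!is_tip])]
  tr <- structure(list(
    edge = edge,
    tip.label = tip_labels,
    Nnode = sum(!is_tip)
  ), class = "phylo", order = "cladewise")
  if (!all(is.na(edge_len))) tr$edge.length <- ifelse(is.na(edge_len), 0, edge_len)
  if (any(nzchar(node_labels))) tr$node.label <- node_labels
  tr
}
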