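#' Read a categorical dataset from a delimited file
#'
#' Expects a header row; the separator is sniffed from the extension
#' (`.csv` = comma, `.tsv`/`.txt` = tab) unless given. Category codes in
#' files are 1-based integers; non-integer category values (strings,
#' arbitrary numeric codes) are mapped to 1..C_j in sorted order and the
#' mapping is stored as `attr(, "category_levels")`. Missing cells are
#' rejected with the row and column named.
#'
#' @param path file path
#' @param items character vector of item column names (default: all
#'   columns except the weight column)
#' @param weight_col optional name of a case-weight column
#' @param sep field separator; default from the extension
#' @param n_categories optional per-item category counts
#' @return an [lc_data] object
#' @export
read_categorical <- function(path, items = NULL, weight_col = NULL,
                             sep = NULL, n_categories = NULL) {
  df <- read_delim_file(path, sep)
  if (!is.null(weight_col) && !weight_col %in% names(df)) {
    stop("weight column '", weight_col, "' not found in ", path, call. = FALSE)
  }
  if (is.null(items)) items <- setdiff(names(df), weight_col)
  missing_items <- setdiff(items, names(df))
  if (length(missing_items) > 0L) {
    stop("columns not found: ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  sub <- df[items]
  for (cn in items) {
    if (anyNA(sub[[cn]])) {
      stop("missing value in column '", cn, "', row ",
           which(is.na(sub[[cn]]))[1], call. = FALSE)
    }
  }
  levels_map <- lapply(sub, function(col) {
    if (is.numeric(col) && all(col == round(col)) && min(col) == 1) {
      NULL  # already 1-based integer codes
    } else {
      sort(unique(col))
    }
  })
  coded <- mapply(function(col, lev) {
    if (is.null(lev)) as.integer(col) else match(col, lev)
  }, sub, levels_map)
  coded <- matrix(as.integer(coded), nrow = nrow(sub),
                  dimnames = list(NULL, items))
  weights <- if (is.null(weight_col)) NULL else as.numeric(df[[weight_col]])
  if (!is.null(weights) && anyNA(weights)) {
    stop("missing weight in row ", which(is.na(weights))[1], call. = FALSE)
  }
  d <- lc_data(coded, weights = weights, item_labels = items,
               n_categories = n_categories)
  attr(d, "category_levels") <- levels_map
  d
}

read_delim_file <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)
  df
}

#' Write a categorical dataset to a delimited file
#'
#' Inverse of [read_categorical()] for 1-based integer codes; the weight
#' column is written only when weights are not all 1.
#'
#' @param data an [lc_data] object
#' @param path output path (`.csv` or `.tsv`)
#' @param weight_col name of the weight column when written
#' @return the path, invisibly
#' @export
write_categorical <- function(data, path, weight_col = "weight") {
  df <- as.data.frame(data$responses)
  names(df) <- data$item_labels
  if (any(data$weights != 1)) df[[weight_col]] <- data$weights
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a top-2 ranking dataset from a delimited file
#'
#' Wide layout: two columns per item holding the first- and second-choice
#' codes.
#'
#' @param path file path
#' @param first_cols,second_cols column names of the first and second
#'   choices, in matching item order
#' @param weight_col optional weight column name
#' @param sep field separator (default from extension)
#' @param n_alternatives optional per-item alternative counts
#' @return a [ranking_data] object
#' @export
read_ranking <- function(path, first_cols, second_cols, weight_col = NULL,
                         sep = NULL, n_alternatives = NULL) {
  df <- read_delim_file(path, sep)
  need <- c(first_cols, second_cols, weight_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  first <- as.matrix(df[first_cols])
  second <- as.matrix(df[second_cols])
  weights <- if (is.null(weight_col)) NULL else as.numeric(df[[weight_col]])
  ranking_data(first, second, weights, n_alternatives,
               item_labels = sub("_?(first|1)$", "", first_cols))
}

# one plain-list representation per node, shared by JSON and DOT export
node_to_list <- function(node) {
  out <- list(label = node$label, size = node$size, depth = node$depth)
  if (!is.null(node$split_decision)) {
    out$criterion_no_split <- unname(node$split_decision["no_split"])
    out$criterion_split <- unname(node$split_decision["split"])
  }
  if (!is.null(node$split_model)) {
    prof <- node_profile(node)
    out$child_proportions <- prof$proportions
    if (!is.null(prof$response_probs)) {
      out$profile <- lapply(prof$response_probs, function(m) {
        unname(as.matrix(m))
      })
    } else {
      out$profile <- lapply(prof$beta, function(m) unname(as.matrix(m)))
    }
  }
  out$children <- lapply(node$children, node_to_list)
  out
}

#' Export a latent class tree
#'
#' `"json"` writes the nested node structure (label, size, split
#' criterion values, class profiles); `"dot"` writes a Graphviz digraph
#' with size-annotated nodes, suitable for `dot -Tpdf`.
#'
#' @param tree an `lct_tree` from [grow_tree()]
#' @param path output file path
#' @param format `"json"` or `"dot"`
#' @return the path, invisibly
#' @export
write_tree <- function(tree, path, format = c("json", "dot")) {
  format <- match.arg(format)
  stopifnot(inherits(tree, "lct_tree"))
  if (format == "json") {
    obj <- list(n_total = tree$n_total, criterion = tree$criterion,
                settings = tree$settings[setdiff(names(tree$settings), "adapter")],
                model = tree$settings$adapter,
                root = node_to_list(tree$root))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    lines <- c("digraph lct {", "  node [shape=box];")
    walk <- function(node) {
      lab <- if (node$label == "0") "root" else node$label
      lines <<- c(lines, sprintf('  "n%s" [label="%s\\nsize %.1f"];',
                                 node$label, lab, node$size))
      for (ch in node$children) {
        lines <<- c(lines, sprintf('  "n%s" -> "n%s";', node$label, ch$label))
        walk(ch)
      }
    }
    walk(tree$root)
    lines <- c(lines, "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Render the class-size layout of a tree as text
#'
#' One line per node, indented by depth, showing label and size — a
#' plain-text analogue of the class-size layout diagrams used for
#' latent class trees.
#'
#' @param tree an `lct_tree`
#' @return character vector of lines
#' @export
render_tree_text <- function(tree) {
  stopifnot(inherits(tree, "lct_tree"))
  lines <- character(0)
  walk <- function(node) {
    lab <- if (node$label == "0") "root" else node$label
    lines <<- c(lines, sprintf("%s%s (%.1f)",
                               strrep("  ", node$depth), lab, node$size))
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  lines
}
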