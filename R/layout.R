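#' Generate 384-well plate layouts with dispersed control wells
#'
#' Builds one or more 16 x 24 plate layouts in which control wells (neutral
#' NTC, positive crLIS1-style, editing crPLK1-style, optionally chemical
#' controls) are scattered across the plate rather than grouped in a block,
#' and the remaining wells are filled with library crRNA pools. The default
#' control design mirrors a genome-wide arrayed screen: 38 NTC, 13 positive
#' and 13 editing control wells per plate, leaving 320 library wells.
#'
#' Library genes are assigned by cycling `library_genes` across the library
#' wells of all plates in order, so a gene list shorter than the total number
#' of library wells yields replicate wells per pool.
#'
#' @param n_plates Number of plates.
#' @param control_design Named integer vector mapping role to wells per plate.
#'   Valid roles: `NTC`, `POS_LIS1`, `EDIT_PLK1`, `NOCODAZOLE`, `VEHICLE`.
#' @param library_genes Character vector of gene identifiers for library
#'   wells. May be empty only if the control design saturates the plate.
#' @param seed Integer seed controlling where control wells land.
#' @return A data.frame with columns `plate_id`, `row`, `col`, `role`,
#'   `crrna_pool`, `gene`; 384 rows per plate.
#' @examples
#' lay <- generate_plate_layout(1, library_genes = paste0("g", 1:320), seed = 1)
#' table(lay$role)
#' @export
generate_plate_layout <- function(n_plates = 1,
                                  control_design = c(NTC = 38, POS_LIS1 = 13, EDIT_PLK1 = 13),
                                  library_genes = character(),
                                  seed = 1) {
  roles <- c("NTC", "POS_LIS1", "EDIT_PLK1", "NOCODAZOLE", "VEHICLE")
  if (length(control_design) && is.null(names(control_design)))
    stop("control_design must be a named vector of role counts")
  bad <- setdiff(names(control_design), roles)
  if (length(bad)) stop("unknown control roles: ", paste(bad, collapse = ", "))
  n_ctrl <- sum(control_design)
  if (n_ctrl > 384) stop("control design requests ", n_ctrl, " wells; a plate has 384")
  n_lib <- 384 - n_ctrl
  if (n_lib > 0 && length(library_genes) == 0)
    stop("library_genes is empty but the design leaves ", n_lib, " library wells per plate")

  grid <- expand.grid(row = 1:16, col = 1:24, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$row, grid$col), , drop = FALSE]

  plates <- vector("list", n_plates)
  lib_cursor <- 0L
  n_genes <- length(library_genes)
  for (p in seq_len(n_plates)) {
    set.seed(well_seed(seed, p, 0L, 0L))
    role <- rep("LIBRARY", 384)
    # scatter control wells: a seeded draw without replacement disperses them
    ctrl_pos <- sample.int(384, n_ctrl)
    off <- 0L
    for (r in names(control_design)) {
      k <- control_design[[r]]
      if (k > 0) role[ctrl_pos[(off + 1L):(off + k)]] <- r
      off <- off + k
    }
    gene <- rep("", 384)
    pool <- rep("", 384)
    is_lib <- role == "LIBRARY"
    if (any(is_lib)) {
      idx <- (lib_cursor + seq_len(sum(is_lib)) - 1L) %% n_genes + 1L
      gene[is_lib] <- library_genes[idx]
      lib_cursor <- lib_cursor + sum(is_lib)
      pool[is_lib] <- paste0("pool_", gene[is_lib])
    }
    pool[role == "NTC"] <- "pool_NTC"
    pool[role == "POS_LIS1"] <- "pool_LIS1"
    pool[role == "EDIT_PLK1"] <- "pool_PLK1"
    plates[[p]] <- data.frame(
      plate_id = paste0("plate_", p),
      row = grid$row, col = grid$col,
      role = role, crrna_pool = pool, gene = gene,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, plates)
  rownames(out) <- NULL
  out
}

#' Validate a plate-layout table
#'
#' Checks the schema and invariants of a plate layout: expected columns, rows
#' 1-16 and columns 1-24, exactly 384 unique well positions per plate, known
#' roles, and a gene identifier on every library well.
#'
#' @param layout Plate-layout data.frame (see [generate_plate_layout()]).
#' @return Invisibly, a character vector of error messages (empty when valid).
#'   Attribute `"warnings"` carries non-fatal notes.
#' @export
validate_plate_layout <- function(layout) {
  errs <- character()
  need <- c("plate_id", "row", "col", "role", "crrna_pool", "gene")
  miss <- setdiff(need, names(layout))
  if (length(miss)) {
    return(invisible(paste0("missing columns: ", paste(miss, collapse = ", "))))
  }
  if (any(layout$row < 1 | layout$row > 16))
    errs <- c(errs, "row outside 1-16")
  if (any(layout$col < 1 | layout$col > 24))
    errs <- c(errs, "col outside 1-24")
  roles <- c("NTC", "POS_LIS1", "EDIT_PLK1", "LIBRARY", "NOCODAZOLE", "VEHICLE")
  if (!all(layout$role %in% roles))
    errs <- c(errs, "unknown role value")
  key <- paste(layout$plate_id, layout$row, layout$col)
  if (anyDuplicated(key))
    errs <- c(errs, "duplicate (plate, row, col) well positions")
  cnt <- table(layout$plate_id)
  if (any(cnt != 384))
    errs <- c(errs, "plates must have exactly 384 wells")
  if (any(layout$role == "LIBRARY" & !nzchar(layout$gene)))
    errs <- c(errs, "LIBRARY well without gene id")
  invisible(errs)
}
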