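# CSV readers and writers for the pipeline's file formats.
#
# Datasets: one row per (molecule, target) affinity record with columns
#   smiles,id[,target,delta_g|ki|ic50[,unit],mw,logp,nhd,nha]
# Latents: id,z0..z{d-1}. Properties: id + the ten screened columns.

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  fields <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(fields) > 1L) {
    bad <- which(fields != fields[1L])
    if (length(bad) > 0L) {
      stop_data("ragged CSV ", path, ": line ", bad[1L] + 0L, " has ",
                fields[bad[1L]], " fields, header has ", fields[1L])
    }
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop_data("malformed header in ", path, ": missing column(s) ",
              paste(miss, collapse = ", "))
  }
  df
}

#' Read a molecule dataset
#'
#' Reads a molecule/affinity CSV and normalizes affinities to binding free
#' energy in kcal/mol: a `delta_g` column is used as-is; otherwise a `ki`
#' column (with optional `unit` column: M, mM, uM or nM; default M) is
#' converted through [ki_to_delta_g()]; otherwise an `ic50` column is first
#' halved to Ki ([ic50_to_ki()]). A row giving Ki = 0.1 uM therefore loads
#' as delta_g = -9.54 kcal/mol (2 d.p.).
#'
#' @param path CSV path with at least `smiles` and `id` columns.
#' @return data.frame of molecule records (validated).
#' @export
read_dataset <- function(path) {
  df <- .read_csv_checked(path, c("smiles", "id"))
  has <- function(col) col %in% names(df) && nrow(df) > 0L
  if (!has("delta_g")) {
    unit <- if (has("unit")) df$unit else "M"
    if (has("ki")) {
      df$delta_g <- ki_to_delta_g(to_molar(df$ki, unit))
    } else if (has("ic50")) {
      df$delta_g <- ki_to_delta_g(ic50_to_ki(to_molar(df$ic50, unit)))
    }
  }
  df$id <- as.character(df$id)
  df$smiles <- as.character(df$smiles)
  validate_molecules(df)
  df
}

# Doubles need 17 significant digits to round-trip through text exactly;
# write.csv stops at 15, so numeric columns are formatted explicitly.
.write_csv_exact <- function(df, path) {
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a molecule or lead table
#'
#' Numeric columns are written with enough digits that reading the file
#' back reproduces them exactly.
#'
#' @param path output CSV path.
#' @param leads data.frame to write.
#' @export
write_leads <- function(path, leads) {
  .write_csv_exact(leads, path)
}

#' Read latent vectors
#'
#' @param path CSV with `id` and `z0..z{d-1}` columns.
#' @return data.frame; use [latent_matrix()] for the numeric matrix.
#' @export
read_latents <- function(path) {
  df <- .read_csv_checked(path, "id")
  zc <- grep("^z[0-9]+$", names(df), value = TRUE)
  if (length(zc) == 0L) stop_data("no z0..z{d-1} columns in ", path)
  if (nrow(df) > 0L && !all(vapply(df[zc], is.numeric, logical(1)))) {
    stop_data("non-numeric latent entries in ", path)
  }
  df$id <- as.character(df$id)
  df
}

#' Write latent vectors
#'
#' @param path output CSV path.
#' @param ids molecule ids.
#' @param z numeric matrix of latent vectors, rows aligned with `ids`.
#' @export
write_latents <- function(path, ids, z) {
  z <- as.matrix(z)
  colnames(z) <- paste0("z", seq_len(ncol(z)) - 1L)
  .write_csv_exact(cbind(data.frame(id = as.character(ids),
                                    stringsAsFactors = FALSE),
                         as.data.frame(z)),
                   path)
}

#' Read a property-profile table
#'
#' @param path CSV with `id` plus the ten screened property columns
#'   (`caco2, f20, pgp_sub, pgp_inh, vd, t_half, fdamdd, sas, logp, logs`).
#' @return data.frame of profiles.
#' @export
read_properties <- function(path) {
  df <- .read_csv_checked(path, c("id", .property_names))
  df$id <- as.character(df$id)
  df
}
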