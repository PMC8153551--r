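# Small in-code fixtures shared across test files.

checklist_rows <- function(full_name, status = "accepted", accepted_ref = "") {
  n <- length(full_name)
  data.frame(full_name = full_name, status = rep_len(status, n),
             accepted_ref = rep_len(accepted_ref, n), stringsAsFactors = FALSE)
}

# a tiny hand-built checklist with one synonym and one infraspecific taxon
tiny_checklist <- function() {
  checklist_rows(
    full_name = c(
      "Achillea millefolium L.",
      "Achillea millefolium L. subsp. sudetica (Opiz) Oborny",
      "Huperzia selago (L.) Bernh. ex Schrank & Mart. subsp. selago",
      "Calendula officinalis L.",
      "Achillea sudetica Opiz"),
    status = c("accepted", "accepted", "accepted", "accepted", "synonym"),
    accepted_ref = c("", "", "", "", "Achillea millefolium L."))
}

write_checklist_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  df <- data.frame(name = rows$full_name, status = rows$status,
                   accepted_name = rows$accepted_ref, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

random_alpha_word <- function(len) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}
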