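# Atom roles and the atom-name <-> role mapping shared by the generator,
# the file readers and every analysis stage.

#' Atom roles recognised by claypep
#'
#' Every atom in a [trajectory()] carries one of these role labels. The
#' analyses never look at chemistry beyond the role: the mineral is reduced
#' to metal and hydroxyl sites, a molecule to its C-terminal carbon and
#' oxygens, backbone nitrogens and (optionally) side-chain oxygens.
#'
#' @return Character vector of the valid role names.
#' @export
#' @examples
#' atom_roles()
atom_roles <- function() {
  c("LDH_METAL_MG", "LDH_METAL_AL", "LDH_HYDROXYL_O", "LDH_HYDROXYL_H",
    "C_TERM_C", "C_TERM_O", "BACKBONE_N", "SIDECHAIN_O", "SIDECHAIN_OTHER",
    "WATER_O", "WATER_H", "COUNTERION")
}

#' Default atom-name to role mapping
#'
#' Force fields differ in atom naming, so the mapping from names found in
#' GRO/PDB/XYZ files to claypep roles is data, not code. The default table
#' ships as an editable YAML file (`system.file("extdata", "atom_roles.yaml",
#' package = "claypep")`); pass your own file to adapt to other naming
#' schemes.
#'
#' @param path Optional path to a YAML file mapping atom names to roles.
#' @return A data.frame with columns `name` and `role`.
#' @export
#' @examples
#' head(role_map())
role_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "atom_roles.yaml", package = "claypep")
  }
  m <- yaml::read_yaml(path)
  df <- data.frame(name = names(m), role = unlist(m, use.names = FALSE),
                   stringsAsFactors = FALSE)
  bad <- setdiff(df$role, atom_roles())
  if (length(bad)) {
    stop("role map contains unknown roles: ", paste(bad, collapse = ", "))
  }
  df
}

# Reverse lookup: role -> canonical atom name(s) used by the writers.
# OT1/OT2 and OD1/OD2 pairs are disambiguated positionally when writing.
role_to_name <- function(roles) {
  first <- c(LDH_METAL_MG = "MG", LDH_METAL_AL = "AL",
             LDH_HYDROXYL_O = "OH", LDH_HYDROXYL_H = "HO",
             C_TERM_C = "CT", C_TERM_O = "OT1", BACKBONE_N = "N",
             SIDECHAIN_O = "OD1", SIDECHAIN_OTHER = "CG",
             WATER_O = "OW", WATER_H = "HW1", COUNTERION = "CL")
  unname(first[roles])
}

names_to_roles <- function(names, map = role_map()) {
  idx <- match(names, map$name)
  if (anyNA(idx)) {
    stop("atom names with no role mapping: ",
         paste(unique(names[is.na(idx)]), collapse = ", "),
         " (extend the role-map YAML to cover them)")
  }
  map$role[idx]
}
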