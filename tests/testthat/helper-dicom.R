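# writes a minimal synthetic explicit-VR little-endian DICOM file for
# round-trip tests of the header reader (the package itself never writes
# DICOM)
write_synthetic_dicom <- function(path, elements) {
  enc_element <- function(group, element, vr, value) {
    if (vr %in% c("DS", "IS")) value <- as.character(value)
    bytes <- charToRaw(value)
    if (length(bytes) %% 2 == 1) bytes <- c(bytes, charToRaw(" "))
    c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
      writeBin(as.integer(element), raw(), size = 2, endian = "little"),
      charToRaw(vr),
      writeBin(length(bytes), raw(), size = 2, endian = "little"),
      bytes)
  }
  out <- c(raw(128), charToRaw("DICM"),
           enc_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  for (el in elements) {
    out <- c(out, enc_element(el$group, el$element, el$vr, el$value))
  }
  writeBin(out, path)
  invisible(path)
}

# tag set describing one plausible exposure
synthetic_exam_elements <- function(thickness = 55, age = "057Y",
                                    with_density = TRUE) {
  el <- list(
    list(group = 0x0008, element = 0x0018, vr = "UI", value = "1.2.3.4"),
    list(group = 0x0008, element = 0x0020, vr = "DA", value = "20180401"),
    list(group = 0x0010, element = 0x0030, vr = "DA", value = "19610315"),
    list(group = 0x0010, element = 0x1010, vr = "AS", value = age),
    list(group = 0x0018, element = 0x1191, vr = "CS", value = "MOLYBDENUM"),
    list(group = 0x0018, element = 0x5101, vr = "CS", value = "CC"),
    list(group = 0x0018, element = 0x7050, vr = "LO", value = "MOLYBDENUM"),
    list(group = 0x0018, element = 0x11a0, vr = "DS", value = thickness),
    list(group = 0x0040, element = 0x0314, vr = "DS", value = 0.38),
    list(group = 0x0040, element = 0x0316, vr = "DS", value = 0.0012),
    list(group = 0x0040, element = 0x8302, vr = "DS", value = 1.8))
  if (with_density) {
    el <- c(el, list(
      list(group = 0x0011, element = 0x1001, vr = "DS", value = 35.2),
      list(group = 0x0011, element = 0x1002, vr = "DS", value = 12.1)))
  }
  el
}
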