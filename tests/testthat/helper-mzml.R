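# Minimal mzML writer used only to exercise the mzR-backed reader on
# programmatically generated fixtures.
enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
spec <- function(i, rt_s, mz, int) {
  sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">
<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>
<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>
<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>
<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/></scan></scanList>
<binaryDataArrayList count="2">
<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/><binary>%s</binary></binaryDataArray>
<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/><binary>%s</binary></binaryDataArray>
</binaryDataArrayList></spectrum>', i, i + 1, length(mz), rt_s, nchar(enc(mz)), enc(mz), nchar(enc(int)), enc(int))
}
write_mini_mzml <- function(path, scans) {
  body <- paste(mapply(function(i, s) spec(i - 1, s$rt * 60, s$mz, s$intensity),
                       seq_along(scans), scans), collapse = "\n")
  xml <- sprintf('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
<cvList count="2">
<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>
</cvList>
<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/><cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/></fileContent></fileDescription>
<softwareList count="1"><software id="sw" version="0"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="sim"/></software></softwareList>
<instrumentConfigurationList count="1"><instrumentConfiguration id="ic"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>
<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>
<run id="run" defaultInstrumentConfigurationRef="ic">
<spectrumList count="%d" defaultDataProcessingRef="dp">
%s
</spectrumList></run></mzML>', length(scans), body)
  writeLines(xml, path)
}
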