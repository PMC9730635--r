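cause,technological,count
contamination,yes,19714313
contusion,yes,13969714
dermatosis,no,6305341
aerosacculitis,no,5055339
arthritis,no,2120165
septicemia,no,1712767
disgusting_aspects,no,1665298
excessive_scalding,yes,1133914
cellulitis,no,889035
others,,478617
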