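# patsr task list v1
# provenance: built-in ex vivo defaults
threshold lo=55 hi=255
bitwise op=AND a=selection b=roi assign=roi
despeckle mode=sweep_keep_largest space=3D target=roi
save_bitmaps label=lung_tissue
analysis3d label=lung_tissue values=basic,additional
model3d label=lung_tissue
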