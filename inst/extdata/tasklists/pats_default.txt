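# patsr task list v1
# provenance: built-in air+tissue defaults
threshold lo=55 hi=255
shrinkwrap diameter=4
reload
threshold lo=0 hi=55
bitwise op=AND a=selection b=roi assign=roi
despeckle mode=sweep_keep_largest space=3D target=roi
optional despeckle mode=sweep_keep_largest space=3D target=roi
save_bitmaps label=aerated_lung
analysis3d label=aerated_lung values=basic
model3d label=aerated_lung
morphology op=closing shape=round radius=40 space=2D target=roi
optional bitwise op=AND a=selection b=roi assign=roi
optional save_bitmaps label=roi_for_modification
reload
threshold lo=55 hi=255
morphology op=erosion shape=round radius=1 space=2D target=selection
bitwise op=AND a=roi b=selection assign=roi
save_bitmaps label=lung_tissue
analysis3d label=lung_tissue values=basic,additional
model3d label=lung_tissue
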