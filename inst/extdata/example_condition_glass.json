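{"stiffness_kpa":10000000,"area_um2":null,"density":"low","cytd_um":0,"lat_um":0,"jas_um":0,"y27_um":0,"bleb_um":0,"mutation":"none"}
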