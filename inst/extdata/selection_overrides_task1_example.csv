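item,action,metric
depth_perception,add,G-DPL
depth_perception,add,G-NOC
depth_perception,add,S-DPL
depth_perception,add,S-DV
depth_perception,remove,Time
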