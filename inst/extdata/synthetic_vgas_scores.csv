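examination_id,tracer,dose_mmolFe_per_kg,ivc_visibility,aa_visibility,background_artifact
ex01,MCP3,0.1,4,4,3
ex02,MCP3,0.1,4,3,3
ex03,MCP3,0.1,4,4,4
ex04,MCP3,0.05,4,3,3
ex05,MCP3,0.05,3,3,3
ex06,MCP3,0.05,4,3,4
ex07,MCP3,0.025,3,2,3
ex08,MCP3,0.025,3,1,2
ex09,Resovist,0.1,3,2,2
ex10,Resovist,0.1,3,1,2
ex11,Resovist,0.1,2,2,1
ex12,Resovist,0.05,2,1,2
ex13,Resovist,0.05,3,1,1
ex14,Resovist,0.05,2,1,2
ex15,Resovist,0.025,2,1,1
ex16,Resovist,0.025,1,1,1
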