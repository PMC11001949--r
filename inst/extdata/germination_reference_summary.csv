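treatment_id,index,mean,sd
GA3_paper_10C,fgp,17,2.4
GA3_paper_10C,mgt,30.3,2.4
GA3_paper_10C,mgr,0.033,0.004
GA3_paper_10C,fdg,26,3.1
GA3_paper_10C,ldg,39,5.2
GA3_paper_10C,cvt,14.9,2.3
GA3_paper_10C,cvg,3.3,0.41
GA3_paper_10C,gri,0.50,0.07
GA3_paper_10C,gi,92,12.3
GA3_paper_10C,t50,28.3,2.9
GA3_paper_15C,fgp,14,1.6
GA3_paper_15C,mgt,36,4.1
GA3_paper_15C,mgr,0.028,0.003
GA3_paper_15C,fdg,32,2.7
GA3_paper_15C,ldg,40,3.5
GA3_paper_15C,cvt,15.7,1.9
GA3_paper_15C,cvg,2.8,0.31
GA3_paper_15C,gri,0.28,0.03
GA3_paper_15C,gi,50,4.3
GA3_paper_15C,t50,32,2.6
GA3_agar_10C,fgp,32,2.5
GA3_agar_10C,mgt,32.5,3.5
GA3_agar_10C,mgr,0.031,0.02
GA3_agar_10C,fdg,25,2.1
GA3_agar_10C,ldg,37,3.0
GA3_agar_10C,cvt,15.8,1.4
GA3_agar_10C,cvg,3.1,0.23
GA3_agar_10C,gri,0.94,0.07
GA3_agar_10C,gi,171,13.2
GA3_agar_10C,t50,32,2.4
GA3_agar_15C,fgp,23,1.9
GA3_agar_15C,mgt,34.4,2.9
GA3_agar_15C,mgr,0.029,0.002
GA3_agar_15C,fdg,29,2.2
GA3_agar_15C,ldg,42,3.3
GA3_agar_15C,cvt,10.4,1.2
GA3_agar_15C,cvg,2.9,0.23
GA3_agar_15C,gri,0.73,0.06
GA3_agar_15C,gi,133,10.6
GA3_agar_15C,t50,33.5,2.8
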